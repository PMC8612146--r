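>whib_syn01 synthetic WhiB-like family member
MTKQRRWHYEMAFIYSQPGTSKYSMFFAPVRHRNHPWGSHKPRRMNQCKVNGTDKDSWNTPLWWEPVAYAHEDTFYQDLPEIMNMKRQKRHLQEMCPN
>whib_syn02 synthetic WhiB-like family member
MQKQRRWHYEMAFLYKHPGGSFRSMFFAPVRHDMHPWGSHKPPRENQLKYNGTDKISWNTPLGEEPVFYAHTDTFYQDHPQAWNQFRQTRHLQTMCKN
>whib_syn03 synthetic WhiB-like family member
MTKQRRWHGGMAFIYSWPCTEKYCKLFAHVLHRVHPWGSRKPRAMNQCKVNGPYEDMWNAPLWWEPVAGAHACTFHQDLPECMNMKRYKRHLSEMFGN
>whib_syn04 synthetic WhiB-like family member
MEKQRYWYYEMAFISVQIWVSRYSMFFHPWRHRNCDWGSHKPLRMNERKVNGTDKDSLRTPLWHPIVAYAHCDTPYQDDPEIMNQKRQKRHLTVMCPN
>whib_syn05 synthetic WhiB-like family member
MTKQRRWHYRMGFIYSQPGKSKYSMFFKNDRHRNHYYGHFKPERGNQCCVNQTFHDYWNTMLWWEYVAYAHEQTASQDLIESMNCKRQHRHLAEMCPN
>whib_syn06 synthetic WhiB-like family member
MTKQEMWHPCMWFIYSQPGTSLGSAFFSPVDHRHHPFGSHLPRRFNQCQVNGTDHDCWNTPLWVEPVAAAHSDTFYQDLDEIMEMKYQKRHLPEMTNL
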