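>lsr2_syn01 synthetic Lsr2-like family member
MRLDFLSPYQWDPSHAAIDDTTQWPCNAWVKHLMWYGYEECMPKCAIYIVTITAGRPAHYWFTIAGWDDRSDERGIHFHRVRCYKKDGTDDIRNRTHGNMGECSMNCYELSF
>lsr2_syn02 synthetic Lsr2-like family member
MHLDELSSYNWDPSMAAIMDRTQGPMDAAHKHLMQYGYEFCEPKCAILIVNYTAERPAHEWFTPAEDDDRSWERGIHFHRVRAYKKDGTDDIRNRTPGQMWERVMNCYEMSF
>lsr2_syn03 synthetic Lsr2-like family member
MTLMFLAWTQWDPSHAGIDDTTQKPCPAWVMHLMAYGYIYCMDKWAIYIVTITAGEPAIGWFWIAAWDDRRPEVGSHFHRVRCSWKDGCDDIRNYTHHPMGHCQMNCYELSF
>lsr2_syn04 synthetic Lsr2-like family member
MRIDCMSPYKWFPNQHAIDQTTQWPQNAWVKNLMWYGYVECMPKCPIYAVTITATRMHHIWFTEHGSDDRSDTRGIHFHCVRNHTKDGTDDIDNSTHGNMGECSMNNYNLSP
>lsr2_syn05 synthetic Lsr2-like family member
MHLTFLSPYQWDPLHAATHDTTQWPINAHVKHWLWLGYEECMCKCRDDIVTITAGGHAHYWFTSAGWFDRSDEVGIHPHRVRCHKMDGHDDIRFRTHGNMCEHSPNTCELYS
>lsr2_syn06 synthetic Lsr2-like family member
MRLDFLDPYKLDPSMAAYDRTTQVPKRAWDGLLMWYLYEFCMPKSAIYIQTSRAGRPAHDWFTIAGWDDRSDERGIAFMRKRCYTKDGTDDHRNETAGNQGECKMLIIELSF
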