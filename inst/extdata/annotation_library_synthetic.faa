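>integrase synthetic annotation-library proxy
METPQMTQFYKCMSKYLCIIIGCDTWTGKCTMTNIWCASSSVMEHNDQAGRELNFYMRQQYARYTYWMEQMEMEGGCERMYNTYKWLFIWSKTNYGDVTFGSIKTLHQQYYPIQGHPQIMRVTPYDKAHWKCVAWPFMRIPEFKHYQIINMSLQFNVLHENQDHQRTEGEDRQYKLWIHRCCHYHITPPFMPKCGPFFMDAISLIIFWKQVLARYRAVVLVWSTVWYQMHPEQLMYRKPVTMSIDLGASLHTDTPFFLHGGVCNSGVTNYCKWTLSGNDDGVCPRQCVHETSVQEQAAIL
>excisionase synthetic annotation-library proxy
MCADKYGDLQKDEEHQYKNQEHWRQEHEARARVCNITWISVWGFHKWPTYIVGVPNWEGGRRMDIWHMLVIGLDTSRLLE
>HTH_3 synthetic annotation-library proxy
MVVSHQNFCMASDGWAGHDGHQGPMHWKSWKHMAMTCHNCWVQCTEHPHRKHHFKSLAYMELNDIRPNYYIVTWVPASQLPMQDKENIPHAMQKI
>ParA synthetic annotation-library proxy
MHMWECPEPKGNLIMEWASTYFRTNHHLSTTLDAKGYRQDTSYCIKMVPPHVIQMWNVMQYYPECSMNCFNPKETHCDESMSWRIGMVLIRNGMEDAACKNFLNNEQMTYTHWPGFYATAHTNGTNFCTERAEETCTYTHPIWGKWQMDQKHMWEPPWYSKIPNLCKMPYEMMMVRNEKSRDTCDWRCDIPVSPPIPYFFENAANWPNQF
>ParB synthetic annotation-library proxy
MRCYEIEWPLYWMEGTTIGIVAMVGPCDEALWKRTSWTHCQPLCTGKGEQCETFWLGSVMCAHTWKDRMSQMSMYEGNHLPGINMGCIMWPNRTDTRWFEHRFIGRKEKTDHMWLIEPQAKGYHGHEYQHAACWFQINELCWNILHLWNWHQSTLFQRCSCLHMQLAWLLQLCHRYYPSG
>glutaredoxin synthetic annotation-library proxy
MEWYEIYQEVLTPLGCAYRWQEWQAAFFLCHWIMKPRLGRDCMWRNTLMPCAMGGIFSEYYAPPRQDIYWQHKSFRADPLKAVQV
>primase synthetic annotation-library proxy
MKLKPYPEPNKTLVCDRILFSAYCCHSGAELDGDDNCYIEDLYENDMEGGYFWKHLFSIPWDIDQGEPSLRCTDAHHAWRSDHYTSINKWSASQWQTFPWFNTICRAHMSYNGKLTYYWSMLIIWYIHEFKDFIMIHNMSAVHPLLDDLYQLPHMLIGDTWVVRYALMCWHFDQAMLYDNSADRCQCRIYVAETSNAFADANRLSGAIQQMTRTHHPNMDLYFNQFHCQIWKRWMVWLFDPSFMEGIWSL
>helicase synthetic annotation-library proxy
MEKCPCPDWQQQHVKLGWWDHEQKMMKMKQHDSFFKHDYSRNFECFCDWPFGKMLEYQIMSLYNQCQFVTGAMAASNKSFAWGVMQMRCVLIASCLHIRAYIHEFWIQGAYQRGYSWTIMMTCDRDNKEQMPKDTVESEWFVWKWNTMRHPEFFLSKELWTIFGWAHLGWAPKERQKLVCHQYFNSMNIFENYLMWIKQRWYAWLHEFDVPQAISSSRAIPVWALSNITHEWGRRRCVVLANNYCEDGGGFIMGCGVAIKGPHNAPSMMVWTGTWASKLCLGRCLLNFVRWLSAEPLWSVREENKDHETAECQTDESVQH
>polymerase synthetic annotation-library proxy
MQIANHMTVHKWLNHECNAKSSSNFCFYGLSCNCNDDWTWALYMMNWKEDRNEGHENASCSAAQKVRKLESAVLLHMVHLKPSHCARPPCPTLIAADINFTNGTNPWSTSRTRYTAPMTNFLLIIPGRCHPMMYHKWELRYKTQHDWPRGLSHIVCFWNLGAGGPANNGPLIEDMEISRWFKVPPSHNKTAQCARKMKRVKIRIEMDQCSDIKGIYIGHKVLVARRQYLADIYQQYPDCNMGSLSNCHHDDEYYPLRTNYHFVDRGGPECCCGVVYMHSSGGRMRQLWFGEEWDYGFTGMPACGLFFATRQAQGRDESCEVMVWAIKIKSYDCGHQLYSKEQVACAYYEQ
>Ku synthetic annotation-library proxy
MYCNAHPLFMMRPQTFCNMVQHFFNHQGVEGHAMVYRDWNAYIEIPCCESLPHVFPPQFACIWDRWPCKLNCFMPYMRPCGPCHPNKVSSHTMQQAFPQKMVIQEAVFLPQNVIMHCNDKCPFVKDQQEGPKPNQQVNLPKDPLHYLSVNSLWCDANFMLSMKLNEFMVCNQKPEHMINALECNWDIVPFEMTHQTWFRFDSWKPLDKPDGNLVTEHGYIHDRDSLWFMNCKHWGYKSQYHWCETHGLQFVCMGHGPCQQWGWQQLTEAE
>RNase_T synthetic annotation-library proxy
MEAMGYNWRPMGLNMNLDLASNSCGNCMACHNRQQWKRNAKELKAPKMQHHQNNTVSVRSLIEMENTIRHVIKFFIEMFEFTNYFRCFYIYHDQRRAFAWMKHYCPHSQNTRFWVWKWRWWPKKFHMEIIYPIKADHSIYYFTQRAFTCYSTNESIWCVGWHYCCMDIPYNGAYAYPCWRSISTEMPPVYTIPESQSEDI
>SSB synthetic annotation-library proxy
MPIIEAPSCYATGWDTGVCDSYGFNMWCKRLECLWTHMKVFPDHDYDEACMHSNPCANKLKARIGGQYAIYFMWQASTCCSGIMTAWHNKWGDSPRPKNLVNVWMPKDDDRCYQDFTGGM
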