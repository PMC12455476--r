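>A1-LCD
GSMASASSSQRGRSGSGNFGGGRGGGFGGNDNFGRGGNFSGRGGFGGSRGGGGYGGSGDGYNGFGNDGSNFGGGGSYNDFGNYNNQSSNFGPMKGGNFGGRSSGGSGGGGQYFAKPRNQGGYGGSSSSSSYGSGRRF
>FUS-LCD
MASNDYTQQATQSYGAYPTQPGQGYSQQSSQPYGQQSYSGYSQSTDTSGYGQSSYSSYGQSQNTGYGTQSTPQGYGSTGGYGSSQSSQSSYGQQSSYPGYGQQPAPSSTSGSYGSSSQSSSYGQPQSGSYSQQPSYGGQQQSYGQQQSYNPPQGYGQQNQYNS
>EWSR1-LCD
MASTDYSTYSQAAAQQGYSAYTAQPTQGYAQTTQAYGQQSYGTYGQPTDVSYTQAQTTATYGQTAYATSYGQPPTGYTTPTAPQAYSQPVQGYGTGAYDTTTATVTTTQASYAAQSAYGTQPAYPAYGQQPAATAPTRPQDGNKPTETSQPQSSTGGYNQPSLGYGQSNYSYPQVPGSYPMQPVTAPPSYPPTSYSSTQPTSYDQSSYSQQNTYGQPSSYGQQSSYGQQSSYGQQPPTSYPPQTGSYSQAPSQYSQQSSSYGQQSSFRQDHPSSMGVYGQ
>TIA1-LCD
MINPVQQQNQIGYPQPYGQWGQWYGNAQQIGQYMPNGWQVPAYGMYGQAWNQQGFNQTQSSAPWMGPNYGVQPPQGQNGSMLPNQPSGYRVAGYETN
>(S9Y)15
SSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSYSSSSSSSSSY
>(S4Y)30
SSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSYSSSSY
>(SSY)50
SSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSYSSY
>(YS)75
YSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYSYS
>(YYS)50
YYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYSYYS
>Y150
YYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYYY
>(S12Y3)10
SSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYYSSSSSSSSSSSSYYY
>(S24Y6)5
SSSSSSSSSSSSSSSSSSSSSSSSYYYYYYSSSSSSSSSSSSSSSSSSSSSSSSYYYYYYSSSSSSSSSSSSSSSSSSSSSSSSYYYYYYSSSSSSSSSSSSSSSSSSSSSSSSYYYYYYSSSSSSSSSSSSSSSSSSSSSSSSYYYYYY
>S120Y30
SSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSSYYYYYYYYYYYYYYYYYYYYYYYYYYYYYY
>(S120Y30)scr
SSSSSSSSSSSSYSSYSYYYYSSSSSSSSSYSSSSSSSSYSSSSYSSSSSSSSYSSSSSSSSSSSSYSSYYYSSSSSSYSYSYSSSSSSSYSSSYSSYSSSSSSSYSSSYYSSSSSYYSYSYSYSSSSSSSSSYSSSSSSSSSSSYSSSS
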