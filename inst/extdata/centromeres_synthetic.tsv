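chrom	cenStartBp	cenEndBp
1	133250000	136750000
2	93250000	96750000
3	97250000	100750000
4	105250000	108750000
5	101300000	108400000
6	50250000	53750000
7	58250000	61750000
8	49250000	52750000
9	70250000	73750000
10	50250000	53750000
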