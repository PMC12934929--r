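# Chicken-like ZW genome spec (approximate Gallus gallus chromosome lengths); convenience, not normative.
system	ZW
id	length	role	effective_length
chr1	196449156	autosome	196449156
chr2	149539284	autosome	149539284
chr3	110642502	autosome	110642502
chr4	90861225	autosome	90861225
chr5	59506338	autosome	59506338
chr6	36220557	autosome	36220557
chr7	36382834	autosome	36382834
chr8	29578256	autosome	29578256
chr9	23733309	autosome	23733309
chr10	20453248	autosome	20453248
chr11	19638187	autosome	19638187
chr12	20119077	autosome	20119077
chr13	17905061	autosome	17905061
chr14	15331188	autosome	15331188
chr15	12703657	autosome	12703657
chr16	2706039	autosome	2706039
chr17	11092391	autosome	11092391
chr18	11623896	autosome	11623896
chr19	10455150	autosome	10455150
chr20	14265659	autosome	14265659
chr21	6970754	autosome	6970754
chr22	4686657	autosome	4686657
chr23	6253421	autosome	6253421
chr24	6478339	autosome	6478339
chr25	3067737	autosome	3067737
chr26	5349051	autosome	5349051
chr27	5228753	autosome	5228753
chr28	5437364	autosome	5437364
chr29	1818525	autosome	1818525
chr30	1650996	autosome	1650996
chr31	1085999	autosome	1085999
chr32	1037161	autosome	1037161
chr33	871510	autosome	871510
chrZ	86044486	homogametic	86044486
chrW	9109940	heterogametic	9109940
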