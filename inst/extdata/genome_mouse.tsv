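# Mouse-like genome spec (GRCm39-style chromosome lengths); convenience, not normative.
system	XY
id	length	role	effective_length
chr1	195154279	autosome	195154279
chr2	181755017	autosome	181755017
chr3	159745316	autosome	159745316
chr4	156860686	autosome	156860686
chr5	151758149	autosome	151758149
chr6	149588044	autosome	149588044
chr7	144995196	autosome	144995196
chr8	130127694	autosome	130127694
chr9	124359700	autosome	124359700
chr10	130530862	autosome	130530862
chr11	121973369	autosome	121973369
chr12	120092757	autosome	120092757
chr13	120883175	autosome	120883175
chr14	125139656	autosome	125139656
chr15	104073951	autosome	104073951
chr16	98008968	autosome	98008968
chr17	95294699	autosome	95294699
chr18	90720763	autosome	90720763
chr19	61420004	autosome	61420004
chrX	169476592	homogametic	169476592
chrY	91455967	heterogametic	91455967
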