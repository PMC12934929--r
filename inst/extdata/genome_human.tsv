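# Human-like genome spec (GRCh38-style chromosome lengths); convenience, not normative.
system	XY
id	length	role	effective_length
chr1	248956422	autosome	248956422
chr2	242193529	autosome	242193529
chr3	198295559	autosome	198295559
chr4	190214555	autosome	190214555
chr5	181538259	autosome	181538259
chr6	170805979	autosome	170805979
chr7	159345973	autosome	159345973
chr8	145138636	autosome	145138636
chr9	138394717	autosome	138394717
chr10	133797422	autosome	133797422
chr11	135086622	autosome	135086622
chr12	133275309	autosome	133275309
chr13	114364328	autosome	114364328
chr14	107043718	autosome	107043718
chr15	101991189	autosome	101991189
chr16	90338345	autosome	90338345
chr17	83257441	autosome	83257441
chr18	80373285	autosome	80373285
chr19	58617616	autosome	58617616
chr20	64444167	autosome	64444167
chr21	46709983	autosome	46709983
chr22	50818468	autosome	50818468
chrX	156040895	homogametic	156040895
chrY	57227415	heterogametic	57227415
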