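gene	feature_class	start	end	strand	coding_bp	stop_codon	printed_density	printed_protein_aa	printed_intron_mean
cox1	protein	1	21743	+	1590	TAA	7.3	529	1550
rnl	rRNA	23389	34087	+	3624	NA	33.9	NA	1769
atp6	protein	36924	37700	+	777	TAA	100.0	258	NA
cox2	protein	45480	52022	+	756	TAA	11.6	251	1929
cox3	protein	58610	61439	+	813	TAA	28.7	270	2017
nad4L	protein	64304	66152	+	273	TAA	14.8	90	1576
nad5	protein	66153	76178	+	2007	TAA	20.0	668	1604
atp8	protein	77128	77286	+	159	TAA	100.0	52	NA
nad2	protein	81572	87656	+	1812	TAA	29.8	603	2137
nad3	protein	87656	88030	+	375	TAA	100.0	124	NA
atp9	protein	103782	104003	-	222	TAA	100.0	73	NA
rns	rRNA	109435	112341	-	1711	NA	58.9	NA	399
cob	protein	119244	126306	-	1272	TAA	18.0	423	1930
nad4	protein	127498	130848	-	1473	TAA	44.0	490	1878
nad6	protein	133402	134382	-	981	TAA	100.0	326	NA
atp6	protein	139006	139782	-	777	TAA	100.0	258	NA
nad1	protein	140738	143807	-	1017	TAG	33.1	338	2053
rps3	protein	150069	151403	+	1335	TAA	100.0	444	NA
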