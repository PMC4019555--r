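amino_acid	anticodon	start	end	strand	printed_length
Ile	GAU	39443	39514	+	72
Ala	UGC	55927	55999	+	73
Trp	CCA	78296	78369	+	74
Asp	GUC	79686	79758	+	73
Phe	GAA	89697	89767	+	71
Thr	UGU	91722	91793	+	72
Gln	UUG	92238	92311	+	74
Lys	UUU	93159	93231	+	73
Tyr	GUA	95474	95557	+	84
Phe	GAA	96533	96603	+	71
Ile	CAU	96632	96704	+	73
Ser	UGA	97243	97328	+	86
Val	UAC	103081	103151	-	71
Ser	GCU	107528	107609	-	82
His	GUG	107979	108050	-	72
Val	UAC	108850	108920	-	71
Met	CAU	113144	113216	-	73
Arg	UCG	114191	114261	-	71
Leu	UAG	114743	114816	-	74
Gly	UCC	117118	117188	-	71
Ile	GAU	137192	137263	-	72
Arg	UCU	146748	146818	-	71
Cys	GCA	148390	148461	-	72
Pro	UGG	153357	153429	+	73
Asn	GUU	153900	153972	+	73
Leu	UAA	154617	154701	+	85
Met	CAU	154736	154807	+	72
Glu	UUC	154832	154902	+	71
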