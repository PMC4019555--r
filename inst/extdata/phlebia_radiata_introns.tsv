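gene	ordinal	length_bp	he_label
cox1	1	1463	GIY-YIG
cox1	2	1540	LAGLIDADG1
cox1	3	1680	LAGLIDADG1
cox1	4	1356	LAGLIDADG2
cox1	5	3420	none
cox1	6	1447	LAGLIDADG1
cox1	7	432	none
cox1	8	1144	LAGLIDADG2
cox1	9	1410	LAGLIDADG2
cox1	10	1649	GIY-YIG
cox1	11	1076	LAGLIDADG1
cox1	12	2004	GIY-YIG
cox1	13	1532	GIY-YIG
nad5	1	1413	LAGLIDADG1
nad5	2	2278	LAGLIDADG2
nad5	3	1405	LAGLIDADG1
nad5	4	1186	LAGLIDADG2
nad5	5	1737	GIY-YIG
rnl	1	1675	LAGLIDADG2
rnl	2	1912	GIY-YIG
rnl	3	1756	LAGLIDADG2
rnl	4	1732	GIY-YIG
cox2	1	2849	GIY-YIG
cox2	2	1152	LAGLIDADG2
cox2	3	1786	GIY-YIG
rns	1	704	none
rns	2	201	none
rns	3	291	none
cob	1	1864	LAGLIDADG1
cob	2	2452	RT
cob	3	1475	LAGLIDADG2
nad2	1	1306	LAGLIDADG2
nad2	2	2967	none
cox3	1	2017	LAGLIDADG2
nad4L	1	1576	LAGLIDADG1
nad4	1	1878	none
nad1	1	2053	LAGLIDADG1
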