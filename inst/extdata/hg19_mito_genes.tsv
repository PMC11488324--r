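gene	start	end	strand	class
D-loop	1	576	+	D-loop
tRNA-Phe	577	647	+	tRNA
12S-rRNA	648	1601	+	rRNA
tRNA-Val	1602	1670	+	tRNA
16S-rRNA	1671	3229	+	rRNA
tRNA-Leu1	3230	3304	+	tRNA
ND1	3307	4262	+	protein
tRNA-Ile	4263	4331	+	tRNA
tRNA-Gln	4329	4400	-	tRNA
tRNA-Met	4402	4469	+	tRNA
ND2	4470	5511	+	protein
tRNA-Trp	5512	5579	+	tRNA
tRNA-Ala	5587	5655	-	tRNA
tRNA-Asn	5657	5729	-	tRNA
tRNA-Cys	5761	5826	-	tRNA
tRNA-Tyr	5826	5891	-	tRNA
COX1	5904	7445	+	protein
tRNA-Ser1	7446	7514	-	tRNA
tRNA-Asp	7518	7585	+	tRNA
COX2	7586	8269	+	protein
tRNA-Lys	8295	8364	+	tRNA
ATP8	8366	8572	+	protein
ATP6	8527	9207	+	protein
COX3	9207	9990	+	protein
tRNA-Gly	9991	10058	+	tRNA
ND3	10059	10404	+	protein
tRNA-Arg	10405	10469	+	tRNA
ND4L	10470	10766	+	protein
ND4	10760	12137	+	protein
tRNA-His	12138	12206	+	tRNA
tRNA-Ser2	12207	12265	+	tRNA
tRNA-Leu2	12266	12336	+	tRNA
ND5	12337	14148	+	protein
ND6	14149	14673	-	protein
tRNA-Glu	14674	14742	-	tRNA
CYTB	14747	15887	+	protein
tRNA-Thr	15888	15953	+	tRNA
tRNA-Pro	15956	16023	-	tRNA
D-loop	16024	16569	+	D-loop
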