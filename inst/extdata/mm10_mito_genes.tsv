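gene	start	end	strand	class
tRNA-Phe	1	68	+	tRNA
12S-rRNA	70	1024	+	rRNA
tRNA-Val	1025	1093	+	tRNA
16S-rRNA	1094	2675	+	rRNA
tRNA-Leu1	2676	2750	+	tRNA
ND1	2751	3707	+	protein
tRNA-Ile	3706	3774	+	tRNA
tRNA-Gln	3772	3842	-	tRNA
tRNA-Met	3845	3913	+	tRNA
ND2	3914	4951	+	protein
tRNA-Trp	4950	5016	+	tRNA
tRNA-Ala	5018	5086	-	tRNA
tRNA-Asn	5089	5161	-	tRNA
tRNA-Cys	5192	5257	-	tRNA
tRNA-Tyr	5258	5325	-	tRNA
COX1	5328	6872	+	protein
tRNA-Ser1	6870	6938	-	tRNA
tRNA-Asp	6942	7011	+	tRNA
COX2	7013	7696	+	protein
tRNA-Lys	7700	7764	+	tRNA
ATP8	7766	7969	+	protein
ATP6	7927	8607	+	protein
COX3	8607	9390	+	protein
tRNA-Gly	9391	9458	+	tRNA
ND3	9459	9806	+	protein
tRNA-Arg	9808	9875	+	tRNA
ND4L	9877	10173	+	protein
ND4	10167	11544	+	protein
tRNA-His	11546	11614	+	tRNA
tRNA-Ser2	11615	11673	+	tRNA
tRNA-Leu2	11674	11744	+	tRNA
ND5	11742	13565	+	protein
ND6	13552	14070	-	protein
tRNA-Glu	14071	14139	-	tRNA
CYTB	14145	15288	+	protein
tRNA-Thr	15289	15355	+	tRNA
tRNA-Pro	15356	15422	-	tRNA
D-loop	15423	16299	+	D-loop
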