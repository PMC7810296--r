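clade	species	biome	habitat	size_class	bristles
A	Eidmanacris_fusca	Atl	str	3	anterior
A	Eidmanacris_melloi	Atl	str	1	anterior
A	Eidmanacris_endophallica	Atl	str	2	anterior
A	Eidmanacris_minuta	Atl	str	0	anterior
C	Eidmanacris_bidentata	Atl	str	1	anterior
E	Eidmanacris_putuhra	Atl	str	1	anterior
G	Eidmanacris_tridentata	Atl	str	1	anterior
G	Eidmanacris_simoesi	Atl	str	1	anterior
G	Eidmanacris_eliethae	Atl	str	2	anterior
I	Eidmanacris_papaveroi	Atl	str	2	anterior
K	Eidmanacris_fontanettiae	Atl	str	1	anterior
M	Eidmanacris_larvaeformis	Atl	str/cav	4	anterior
M	Eidmanacris_septentrionalis	Atl	str/cav	2	anterior
M	Eidmanacris_speluncae	Atl	cav	3	anterior
M	Eidmanacris_multispinosa	Atl	str	3	anterior
N1	Eidmanacris_dissimilis	Atl/Cer	str/cav	2	entire
N1	Eidmanacris_meridionalis	Atl	str/cav	2	entire
N1	Eidmanacris_alboannulata	Atl/Cer	str/cav	3	entire
N1	Eidmanacris_suassunai	Atl	str/cav	3	entire
N2	Eidmanacris_scopula	Cer	cav	3	entire
N2	Eidmanacris_desutterae	Cer	str/cav	3	entire
N2	Eidmanacris_corumbatai	Cer	str/cav	3	entire
N2	Eidmanacris_gigas	Cer	str/cav	3	entire
N2	Eidmanacris_caipira	Atl/Cer	str/cav	5	entire
N2	Eidmanacris_bernardii	Cer	str/cav	4	entire
N2	Eidmanacris_neomarmorata	Cer	cav	3	entire
N2	Eidmanacris_marmorata	Chi	str/cav	4	entire
N2	Eidmanacris_longa	Chi	str/cav	4	entire
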