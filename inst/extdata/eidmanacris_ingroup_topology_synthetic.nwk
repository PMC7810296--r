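((Eidmanacris_fusca,(Eidmanacris_melloi,(Eidmanacris_endophallica,Eidmanacris_minuta))),(Eidmanacris_bidentata,(Eidmanacris_putuhra,((Eidmanacris_tridentata,(Eidmanacris_simoesi,Eidmanacris_eliethae)),(Eidmanacris_papaveroi,(Eidmanacris_fontanettiae,((Eidmanacris_larvaeformis,(Eidmanacris_septentrionalis,(Eidmanacris_speluncae,Eidmanacris_multispinosa))),(((Eidmanacris_dissimilis,Eidmanacris_meridionalis),(Eidmanacris_alboannulata,Eidmanacris_suassunai)),(Eidmanacris_scopula,(Eidmanacris_desutterae,((Eidmanacris_corumbatai,Eidmanacris_gigas),(Eidmanacris_caipira,(Eidmanacris_bernardii,(Eidmanacris_neomarmorata,(Eidmanacris_marmorata,Eidmanacris_longa)))))))))))))));
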