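assay_id	description	n_active	n_inactive
1851_1a2	Cytochrome P450 Panel Assay, cyp1a2	5902	6974
1851_2c19	Cytochrome P450 Panel Assay, cyp2c19	5840	7135
1851_2c9	Cytochrome P450 Panel Assay, cyp2c9	4065	8361
1851_2d6	Cytochrome P450 Panel Assay, cyp2d6	2601	10826
1851_3a4	Cytochrome P450 Panel Assay, cyp3a4	5175	7446
1915	Streptokinase Expression Inhibition	2219	1017
2358	Inhibitors of Protein Phosphatase 1 (PP1)	1006	934
463213	Inhibitors of tim10-1 yeast	4138	3234
463215	Inhibitors of tim10 yeast	2941	1695
488912	Inhibitors of Sentrin-specific protease 8	2491	3705
488915	Inhibitors of Sentrin-specific protease 6	3568	2628
488917	Inhibitors of Sentrin-specific protease 7	4283	1913
488918	Inhibitors of Sentrin-specific proteases	3691	2505
492992	Inhibitors of KCNK9	2094	2820
504607	Inhibitors of Mdm2/MdmX interaction	4825	1406
624504	Inhibitors of the mtPTP	3944	1090
651739	Inhibition of T.cruzi proliferation	4043	1322
651744	NIH/3T3 (mouse embryonic fibroblast) toxicity	3099	2303
652065	Molecules that bind r(CAG) RNA repeats	2965	1286
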