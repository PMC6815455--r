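assay_id	best_single	ensemble
1851_1a2	0.922	0.934
1851_2c19	0.885	0.900
1851_2c9	0.880	0.898
1851_2d6	0.867	0.884
1851_3a4	0.895	0.914
1915	0.758	0.755
2358	0.787	0.803
463213	0.685	0.689
463215	0.630	0.627
488912	0.693	0.698
488915	0.731	0.735
488917	0.814	0.834
488918	0.778	0.799
492992	0.849	0.845
504607	0.694	0.721
624504	0.884	0.897
651739	0.802	0.804
651744	0.899	0.901
652065	0.800	0.826
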