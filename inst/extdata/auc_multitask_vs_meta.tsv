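assay_id	multi_task	meta_learning
1851_1a2	0.938	0.943
1851_2c19	0.903	0.908
1851_2c9	0.907	0.908
1851_2d6	0.861	0.892
1851_3a4	0.897	0.920
1915	0.750	0.764
2358	0.751	0.807
463213	0.676	0.694
463215	0.654	0.634
488912	0.816	0.700
488915	0.873	0.739
488917	0.894	0.841
488918	0.842	0.801
492992	0.829	0.862
504607	0.670	0.726
624504	0.889	0.904
651739	0.825	0.809
651744	0.900	0.909
652065	0.792	0.832
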