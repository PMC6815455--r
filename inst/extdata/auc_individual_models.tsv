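assay_id	PubChem-RF	PubChem-SVM	PubChem-GBM	PubChem-NN	ECFP-RF	ECFP-SVM	ECFP-GBM	ECFP-NN	MACCS-RF	MACCS-SVM	MACCS-GBM	MACCS-NN	SMILES-NN	ensemble
1851_1a2	0.921	0.896	0.900	0.921	0.919	0.906	0.882	0.920	0.912	0.879	0.894	0.912	0.922	0.934
1851_2c19	0.871	0.852	0.848	0.872	0.882	0.871	0.854	0.880	0.874	0.842	0.850	0.885	0.875	0.900
1851_2c9	0.871	0.857	0.851	0.873	0.880	0.866	0.843	0.880	0.858	0.828	0.840	0.870	0.877	0.898
1851_2d6	0.858	0.847	0.832	0.869	0.867	0.850	0.833	0.856	0.854	0.816	0.830	0.852	0.846	0.884
1851_3a4	0.877	0.868	0.865	0.887	0.891	0.887	0.855	0.895	0.867	0.832	0.851	0.875	0.891	0.914
1915	0.754	0.692	0.709	0.722	0.731	0.700	0.700	0.712	0.758	0.716	0.736	0.741	0.701	0.755
2358	0.787	0.705	0.736	0.770	0.780	0.767	0.722	0.761	0.774	0.731	0.763	0.775	0.697	0.803
463213	0.673	0.639	0.652	0.651	0.685	0.652	0.644	0.661	0.668	0.642	0.655	0.651	0.636	0.689
463215	0.620	0.576	0.592	0.604	0.617	0.585	0.598	0.595	0.629	0.600	0.630	0.625	0.587	0.627
488912	0.679	0.643	0.634	0.668	0.693	0.654	0.668	0.675	0.667	0.634	0.650	0.673	0.644	0.698
488915	0.718	0.686	0.679	0.713	0.731	0.693	0.680	0.708	0.692	0.659	0.680	0.693	0.679	0.735
488917	0.808	0.777	0.759	0.805	0.814	0.788	0.760	0.799	0.788	0.726	0.752	0.786	0.780	0.834
488918	0.762	0.745	0.735	0.778	0.778	0.766	0.729	0.767	0.737	0.690	0.708	0.742	0.746	0.799
492992	0.829	0.784	0.783	0.800	0.849	0.807	0.802	0.822	0.825	0.726	0.759	0.790	0.802	0.845
504607	0.694	0.678	0.692	0.686	0.690	0.668	0.673	0.656	0.676	0.640	0.662	0.655	0.649	0.721
624504	0.884	0.850	0.857	0.867	0.884	0.858	0.858	0.861	0.872	0.832	0.862	0.876	0.868	0.897
651739	0.791	0.770	0.773	0.781	0.802	0.782	0.771	0.788	0.779	0.729	0.759	0.754	0.792	0.804
651744	0.884	0.862	0.872	0.885	0.889	0.883	0.875	0.896	0.869	0.829	0.843	0.853	0.899	0.901
652065	0.800	0.752	0.782	0.780	0.785	0.775	0.758	0.774	0.776	0.736	0.759	0.772	0.763	0.826
average	0.794	0.762	0.766	0.786	0.798	0.777	0.763	0.784	0.783	0.741	0.762	0.778	0.771	0.814
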