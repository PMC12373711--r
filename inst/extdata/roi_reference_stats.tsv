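network	scope	region	mean1	sd1	mean2	sd2	p_printed	d_printed
visual	network	Visual network	1.155	0.036	1.155	0.135	0.968	0.00
visual	region	Right fusiform gyrus (lateroventral area)	1.144	0.052	1.156	0.052	0.032	0.23
visual	region	Left posterior parahippocampal gyrus	1.048	0.055	1.059	0.050	0.036	0.21
visual	region	Right caudal lingual gyrus	0.972	0.053	0.984	0.053	0.033	0.23
visual	region	Right middle occipital gyrus	1.052	0.061	1.040	0.053	0.037	0.21
visual	region	Right occipital polar cortex	1.059	0.070	1.045	0.056	0.035	0.22
visual	region	Left inferior occipital gyrus	1.154	0.051	1.166	0.044	0.019	0.25
visual	region	Left lateral superior occipital gyrus	1.194	0.066	1.176	0.064	0.007	0.28
somatomotor	network	Somatomotor network	1.074	0.034	1.076	0.127	0.896	0.02
somatomotor	region	Left superior frontal gyrus (medial area)	1.096	0.056	1.108	0.050	0.036	0.23
somatomotor	region	Right precentral gyrus (head and face region)	1.350	0.088	1.325	0.084	0.005	0.29
somatomotor	region	Right precentral gyrus (upper limb region)	1.222	0.068	1.208	0.064	0.035	0.21
somatomotor	region	Right superior temporal gyrus (area 41/42)	1.028	0.047	1.038	0.043	0.033	0.22
somatomotor	region	Left superior temporal gyrus (TE1.0 and TE1.2)	1.126	0.051	1.141	0.044	0.002	0.32
somatomotor	region	Left superior parietal lobule (postcentral area)	0.840	0.055	0.851	0.043	0.038	0.23
somatomotor	region	Right superior parietal lobule (postcentral area)	0.864	0.051	0.875	0.043	0.030	0.23
somatomotor	region	Right inferior parietal lobule (rostroventral area)	1.228	0.085	1.211	0.068	0.035	0.22
somatomotor	region	Left postcentral gyrus (upper limb, head, and face region)	0.992	0.085	1.010	0.074	0.029	0.23
somatomotor	region	Right postcentral gyrus (area 2)	0.958	0.081	0.976	0.066	0.019	0.25
somatomotor	region	Left postcentral gyrus (trunk region)	0.837	0.094	0.862	0.079	0.007	0.29
somatomotor	region	Right postcentral gyrus (trunk region)	0.862	0.079	0.814	0.083	0.010	0.59
dorsal_attention	network	Dorsal attention network	0.993	0.029	0.994	0.119	0.983	0.01
dorsal_attention	region	Left middle frontal gyrus (ventrolateral area)	0.919	0.618	0.937	0.056	0.003	0.04
dorsal_attention	region	Right inferior frontal gyrus (dorsal area)	1.109	0.070	1.080	0.064	0.000	0.43
dorsal_attention	region	Left precentral gyrus (caudal dorsolateral area)	1.301	0.076	1.280	0.076	0.007	0.28
dorsal_attention	region	Right precentral gyrus (caudal dorsolateral area)	1.228	0.071	1.209	0.067	0.007	0.28
dorsal_attention	region	Right inferior temporal gyrus (ventrolateral area)	1.146	0.069	1.161	0.056	0.027	0.24
dorsal_attention	region	Left superior parietal lobule (caudal area)	0.832	0.060	0.844	0.046	0.028	0.23
dorsal_attention	region	Left postcentral gyrus (area 2)	0.959	0.076	0.975	0.063	0.029	0.23
ventral_attention	network	Ventral attention network	1.123	0.036	1.126	0.133	0.786	0.03
ventral_attention	region	Left inferior frontal gyrus (opercular area)	1.090	0.068	1.063	0.060	0.000	0.42
ventral_attention	region	Left inferior frontal gyrus (ventral area)	1.125	0.084	1.101	0.069	0.003	0.31
ventral_attention	region	Left paracentral lobule (lower limb region)	1.142	0.052	1.156	0.053	0.013	0.27
ventral_attention	region	Left caudoposterior superior temporal sulcus	1.184	0.069	1.159	0.056	0.000	0.40
ventral_attention	region	Right caudoposterior superior temporal sulcus	1.202	0.066	1.189	0.053	0.036	0.22
ventral_attention	region	Right dorsal agranular insula	0.887	0.047	0.897	0.042	0.021	0.23
ventral_attention	region	Right ventral dysgranular and granular insula	1.147	0.074	1.124	0.059	0.001	0.35
ventral_attention	region	Left cingulate gyrus (caudodorsal area)	1.169	0.062	1.183	0.051	0.019	0.25
ventral_attention	region	Right cingulate gyrus (caudodorsal area)	1.151	0.053	1.162	0.046	0.024	0.22
limbic	network	Limbic network	0.951	0.031	0.967	0.114	0.056	0.18
limbic	region	Left orbital gyrus (area 13)	1.013	0.053	0.999	0.044	0.004	0.29
limbic	region	Right orbital gyrus (area 13)	1.130	0.067	1.115	0.052	0.021	0.25
limbic	region	Right superior temporal gyrus (medial area)	1.115	0.067	1.096	0.058	0.004	0.31
limbic	region	Left parahippocampal gyrus (entorhinal cortex)	1.052	0.076	1.035	0.053	0.015	0.26
frontoparietal	network	Frontoparietal network	1.076	0.043	1.076	0.129	0.928	0.00
frontoparietal	region	Left superior frontal gyrus (medial area)	1.246	0.097	1.226	0.085	0.039	0.22
frontoparietal	region	Right middle frontal gyrus (dorsal area)	0.907	0.056	0.919	0.052	0.038	0.22
frontoparietal	region	Left middle frontal gyrus (dorsolateral area)	0.970	0.054	0.982	0.050	0.026	0.23
frontoparietal	region	Right middle frontal gyrus (dorsolateral area)	0.936	0.055	0.949	0.048	0.019	0.25
frontoparietal	region	Right middle frontal gyrus (area 46)	0.784	0.061	0.799	0.054	0.012	0.26
frontoparietal	region	Left inferior frontal sulcus	1.079	0.065	1.063	0.055	0.011	0.27
frontoparietal	region	Right inferior frontal sulcus	1.176	0.081	1.149	0.067	0.001	0.37
frontoparietal	region	Right orbital gyrus (lateral area)	1.010	0.055	1.023	0.042	0.010	0.27
frontoparietal	region	Left inferior temporal gyrus (caudolateral area)	1.074	0.057	1.088	0.051	0.011	0.26
default	network	Default network	1.075	0.025	1.079	0.125	0.609	0.04
default	region	Left middle frontal gyrus (ventrolateral area)	0.912	0.064	0.927	0.061	0.023	0.24
default	region	Left inferior frontal gyrus (caudal area)	1.157	0.075	1.138	0.066	0.009	0.27
default	region	Right inferior frontal gyrus (caudal area)	1.050	0.068	1.031	0.062	0.005	0.29
default	region	Left inferior frontal gyrus (rostral area)	1.080	0.062	1.092	0.051	0.043	0.21
default	region	Left orbital gyrus (medial area)	1.118	0.064	1.102	0.052	0.009	0.28
default	region	Right orbital gyrus (medial area)	1.077	0.049	1.067	0.045	0.041	0.21
default	region	Left orbital gyrus (orbital area)	1.233	0.091	1.216	0.069	0.035	0.21
default	region	Left superior temporal gyrus (rostral area)	1.184	0.083	1.168	0.068	0.034	0.21
default	region	Left anterior superior temporal sulcus	0.915	0.083	0.931	0.070	0.038	0.21
default	region	Right rostroposterior superior temporal sulcus	1.160	0.065	1.142	0.052	0.005	0.31
default	region	Right precuneus (area 31)	0.861	0.079	0.878	0.066	0.026	0.24
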