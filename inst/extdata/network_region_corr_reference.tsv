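network	region	r_printed	p_printed
visual	Right caudal lingual gyrus	-0.150	0.003
somatomotor	Left superior parietal lobule (postcentral area)	-0.180	NA
somatomotor	Right inferior parietal lobule (rostroventral area)	0.157	0.002
somatomotor	Right postcentral gyrus (trunk region)	-0.150	0.003
dorsal_attention	Left postcentral gyrus (area 2)	-0.149	0.004
ventral_attention	Right ventral dysgranular and granular insula	0.174	0.001
frontoparietal	Right middle frontal gyrus (dorsal area)	-0.181	NA
frontoparietal	Left superior frontal gyrus (medial area)	0.170	0.001
frontoparietal	Left middle frontal gyrus (inferior frontal junction)	-0.230	NA
frontoparietal	Left inferior frontal sulcus	0.175	0.001
frontoparietal	Right orbital gyrus (lateral area)	0.173	0.001
frontoparietal	Right inferior frontal sulcus	0.153	0.003
frontoparietal	Right middle frontal gyrus (area 46)	-0.152	0.003
frontoparietal	Right middle frontal gyrus (inferior frontal junction)	-0.166	0.001
default	Left middle frontal gyrus (ventrolateral area)	-0.202	NA
default	Left inferior frontal gyrus (rostral area)	-0.181	NA
default	Right orbital gyrus (medial area)	0.151	0.003
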