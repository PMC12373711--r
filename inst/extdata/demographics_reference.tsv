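characteristic	type	count1	mean1	sd1	count2	mean2	sd2	p_printed
age	continuous	NA	53.75	7.78	NA	53.00	18.42	0.613
male	binary	101	NA	NA	132	NA	NA	0.246
bmi	continuous	NA	24.22	3.19	NA	24.02	3.08	0.540
fbs	continuous	NA	5.78	1.60	NA	5.55	1.20	0.104
smoking	binary	28	NA	NA	35	NA	NA	0.890
hypertension	binary	52	NA	NA	39	NA	NA	0.016
diabetes	binary	30	NA	NA	26	NA	NA	0.245
hyperlipidemia	binary	44	NA	NA	58	NA	NA	0.562
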