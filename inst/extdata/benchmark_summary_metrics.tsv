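dataset	model	acc_mean	acc_sd	sen_mean	sen_sd	spe_mean	spe_sd	mcc_mean	mcc_sd	bacc_mean	bacc_sd
human_balanced	rp_fft	93.54	1.15	87.12	1.87	100.00	0.00	87.83	2.01	NA	NA
yeast_balanced	rp_fft	82.96	1.48	94.94	2.63	71.02	4.73	68.05	1.95	NA	NA
human	rp_fft	96.28	0.22	81.48	2.43	97.62	0.35	76.46	1.29	89.55	1.08
yeast	rp_fft	91.87	0.82	48.81	4.50	97.42	0.45	54.62	4.25	73.12	2.30
human	svm_fft	93.68	0.36	23.80	2.82	100.00	0.00	47.13	2.82	61.90	1.41
yeast	svm_fft	90.63	0.33	17.79	3.80	100.00	0.00	39.95	4.17	58.90	1.90
yeast	rp_svd	88.73	0.75	10.25	2.93	98.86	0.43	19.76	2.96	54.55	1.31
yeast	rp_dct	90.35	0.84	20.38	2.62	99.36	0.32	37.57	1.74	59.87	1.18
yeast	rp_cov	91.93	0.81	42.43	4.82	98.31	0.25	53.10	4.91	70.37	2.49
yeast	slipper	71.90	NA	69.72	NA	72.18	NA	28.42	NA	70.95	NA
yeast	dxecppi	87.46	NA	29.44	NA	94.93	NA	28.25	NA	62.19	NA
yeast	ppievo	66.28	NA	60.14	NA	87.46	NA	18.01	NA	73.80	NA
yeast	locfuse	66.66	NA	55.49	NA	68.10	NA	15.77	NA	61.80	NA
yeast	crs	72.69	NA	59.58	NA	74.37	NA	23.68	NA	66.98	NA
yeast	spar	76.96	NA	53.24	NA	80.02	NA	24.84	NA	66.63	NA
human	slipper	91.10	NA	47.26	NA	95.06	NA	41.97	NA	71.16	NA
human	dxecppi	30.90	NA	87.08	NA	25.83	NA	8.25	NA	56.46	NA
human	ppievo	78.04	NA	87.83	NA	25.82	NA	20.82	NA	56.83	NA
human	locfuse	80.66	NA	50.83	NA	80.50	NA	20.26	NA	65.67	NA
human	crs	91.54	NA	34.17	NA	96.72	NA	36.33	NA	65.45	NA
human	spar	92.09	NA	33.33	NA	97.40	NA	38.36	NA	65.37	NA
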