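dataset	model	fold	acc	sen	spe	mcc	bacc
human_balanced	rp_fft	1	94.44	88.28	100.00	89.36	NA
human_balanced	rp_fft	2	92.53	85.37	100.00	86.07	NA
human_balanced	rp_fft	3	92.19	85.48	100.00	85.51	NA
human_balanced	rp_fft	4	93.75	86.76	100.00	88.08	NA
human_balanced	rp_fft	5	94.81	89.73	100.00	90.12	NA
yeast_balanced	rp_fft	1	80.99	97.12	65.52	65.71	NA
yeast_balanced	rp_fft	2	83.45	92.14	75.00	68.03	NA
yeast_balanced	rp_fft	3	82.04	97.89	66.20	67.57	NA
yeast_balanced	rp_fft	4	84.86	95.14	74.29	71.13	NA
yeast_balanced	rp_fft	5	83.45	92.41	74.10	67.83	NA
human	rp_fft	1	96.23	79.51	97.74	75.72	88.63
human	rp_fft	2	96.20	80.34	97.65	75.89	89.00
human	rp_fft	3	96.58	82.49	97.89	78.61	90.19
human	rp_fft	4	96.40	79.78	97.79	75.40	88.79
human	rp_fft	5	96.00	85.28	97.01	76.68	91.15
yeast	rp_fft	1	91.32	50.00	96.73	53.09	73.37
yeast	rp_fft	2	91.72	47.33	97.81	55.35	72.57
yeast	rp_fft	3	92.20	49.63	97.39	54.80	73.51
yeast	rp_fft	4	91.00	42.36	97.36	49.06	69.86
yeast	rp_fft	5	93.09	54.74	97.83	60.82	76.29
human	svm_fft	1	93.55	22.22	100.00	45.57	61.11
human	svm_fft	2	93.64	23.79	100.00	47.17	61.90
human	svm_fft	3	93.21	20.54	100.00	43.73	60.27
human	svm_fft	4	94.19	24.34	100.00	47.86	62.17
human	svm_fft	5	93.82	28.09	100.00	51.30	64.05
yeast	svm_fft	1	90.11	14.58	100.00	36.22	57.29
yeast	svm_fft	2	90.84	24.00	100.00	46.62	62.00
yeast	svm_fft	3	90.76	14.81	100.00	36.64	57.41
yeast	svm_fft	4	90.51	18.06	100.00	40.38	59.03
yeast	svm_fft	5	90.92	17.52	100.00	39.87	58.76
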