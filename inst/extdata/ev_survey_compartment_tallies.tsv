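assignment	misev2018	kowal_f3_100k	kugeratski_core_exosome	kugeratski_cell_exosome
cytosol	2	94	82	109
endoplasmic reticulum	6	79	42	108
golgi	0	4	2	15
lysosome	2	20	2	27
mitochondria	45	90	78	240
nucleus	9	68	112	429
nucleus-chromatin	8	3	10	35
peroxisome	0	6	3	9
plasma membrane	29	127	34	128
proteasome	0	32	27	29
ribosome 40S	30	29	23	31
ribosome 60S	47	39	39	44
unknown	94	995	454	1349
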