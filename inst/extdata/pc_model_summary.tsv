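n_pcs	n_imputed	mean_cv_accuracy	mean_validation_accuracy	n_replicated	pct_replicated_printed
5	7971	0.20	0.013	2713	34
10	12875	0.25	0.090	6324	49
20	13717	0.27	0.065	6021	44
40	14038	0.29	0.057	6227	44
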