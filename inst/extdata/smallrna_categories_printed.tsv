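category	count_delay	pct_delay_printed	count_activation	pct_activation_printed
miRNA	3972448	74.52	4302233	76.57
piRNA	11912	0.22	8565	0.15
tRNA	9900	0.19	12345	0.22
rRNA	9377	0.18	14823	0.26
snRNA	434	0.01	525	0.01
snoRNA	12875	0.24	7847	0.14
mRNA	18321	0.34	26607	0.47
genomic	30611	0.57	46954	0.84
unknown	1268643	23.78	1198789	21.34
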