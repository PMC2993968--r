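rank	tpm_activation	tpm_delay	sequence
1	6756	7054	TAGCTTATCAGACTGATGTTGA
2	8427	2313	TAGCTTATCAGACTGATGTTGAC
3	3781	4214	TAGCTTATCAGACTGATGTTG
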