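mirna	tpm_activation	tpm_delay	fold_printed
mmu-miR-423-5p	4273	3452	1.24
mmu-miR-221	1095	868	1.26
mmu-miR-17*	239	188	1.27
mmu-let-7f	128615	101036	1.27
mmu-miR-320	13741	10754	1.28
mmu-let-7d	24228	18731	1.29
mmu-miR-98	334	257	1.30
mmu-miR-345-3p	274	210	1.30
mmu-miR-128	227	169	1.35
mmu-miR-145*	106	78	1.37
mmu-miR-21	14877	10297	1.44
mmu-miR-33	108	63	1.71
mmu-miR-341	127	70	1.81
mmu-miR-92a	1411	733	1.93
mmu-miR-298	329	130	2.53
mmu-miR-134	207	80	2.60
mmu-miR-21*	152	52	2.91
mmu-miR-7a	102	30	3.42
mmu-miR-146b	8297	2355	3.52
mmu-miR-805	437	118	3.71
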