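id	tags_delay	tags_activation	mature_sequence
nov-miR-1	101	54	ggggugugcucagagcagguggccu
nov-miR-2	4	20	acccgucccguucguccccgga
nov-miR-3	8	7	aggggagcuagguagaaagcca
nov-miR-4	75	76	auuggaguucaugcaaguucu
nov-miR-5	11	5	cccuggaaggagacguggauuc
nov-miR-6	70	107	cuaaggcaggcagacuucagugu
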