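statistic	delay	activation
total_tags	9912459	12869487
total_tags_no_singleton	8683980	11039265
unique_tags	356981	348124
unique_tags_no_singleton	151876	155218
unique_mapped	51727	51766
unique_single_match	45147	45144
unique_two_match	5451	5463
unique_multiple_match	1129	1159
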