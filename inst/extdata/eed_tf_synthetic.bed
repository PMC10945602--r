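Eed_region	20906	21732	TF_region_2	0	.
Eed_region	25057	26322	TF_region_1	0	.
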