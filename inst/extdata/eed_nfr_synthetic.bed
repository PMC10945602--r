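Eed_region	3000	3200	NFR3	0	.
Eed_region	6500	6700	NFR4	0	.
Eed_region	10000	10200	NFR5	0	.
Eed_region	13500	13700	NFR6	0	.
Eed_region	17000	17200	NFR7	0	.
Eed_region	20400	20750	NFR2	0	.
Eed_region	24650	25000	NFR1	0	.
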