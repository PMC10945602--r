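Eed_region	48	98	LH_peak1	0	.
Eed_region	419	469	LH_peak2	0	.
Eed_region	944	994	LH_peak3	0	.
Eed_region	1504	1554	LH_peak4	0	.
Eed_region	1901	1951	LH_peak5	0	.
Eed_region	2505	2555	LH_peak6	0	.
Eed_region	3248	3298	LH_peak7	0	.
Eed_region	3826	3876	LH_peak8	0	.
Eed_region	4221	4271	LH_peak9	0	.
Eed_region	4785	4835	LH_peak10	0	.
Eed_region	5372	5422	LH_peak11	0	.
Eed_region	5959	6009	LH_peak12	0	.
Eed_region	6401	6451	LH_peak13	0	.
Eed_region	7162	7212	LH_peak14	0	.
Eed_region	7777	7827	LH_peak15	0	.
Eed_region	8349	8399	LH_peak16	0	.
Eed_region	8747	8797	LH_peak17	0	.
Eed_region	9337	9387	LH_peak18	0	.
Eed_region	9901	9951	LH_peak19	0	.
Eed_region	10612	10662	LH_peak20	0	.
Eed_region	11025	11075	LH_peak21	0	.
Eed_region	11665	11715	LH_peak22	0	.
Eed_region	12264	12314	LH_peak23	0	.
Eed_region	12842	12892	LH_peak24	0	.
Eed_region	13225	13275	LH_peak25	0	.
Eed_region	13944	13994	LH_peak26	0	.
Eed_region	14570	14620	LH_peak27	0	.
Eed_region	15137	15187	LH_peak28	0	.
Eed_region	15579	15629	LH_peak29	0	.
Eed_region	16167	16217	LH_peak30	0	.
Eed_region	16705	16755	LH_peak31	0	.
Eed_region	17436	17486	LH_peak32	0	.
Eed_region	17844	17894	LH_peak33	0	.
Eed_region	18419	18469	LH_peak34	0	.
Eed_region	19004	19054	LH_peak35	0	.
Eed_region	19548	19598	LH_peak36	0	.
Eed_region	19935	19985	LH_peak37	0	.
Eed_region	20798	20848	LH_peak38	0	.
Eed_region	21374	21424	LH_peak39	0	.
Eed_region	21924	21974	LH_peak40	0	.
Eed_region	22281	22331	LH_peak41	0	.
Eed_region	22840	22890	LH_peak42	0	.
Eed_region	23367	23417	LH_peak43	0	.
Eed_region	23934	23984	LH_peak44	0	.
Eed_region	24356	24406	LH_peak45	0	.
Eed_region	25218	25268	LH_peak46	0	.
Eed_region	25842	25892	LH_peak47	0	.
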