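sex	ga_week	weight_p10_g	weight_median_g	weight_sd_g	hc_p3_cm	hc_median_cm	hc_sd_cm
male	24	519	660	110	20.1	22	1
male	25	594	753	124	21	22.9	1.02
male	26	687	867	140	21.8	23.8	1.05
male	27	796	1000	159	22.6	24.6	1.07
male	28	919	1150	180	23.4	25.5	1.1
male	29	1057	1316	202	24.2	26.4	1.13
male	30	1207	1497	227	25	27.2	1.15
male	31	1368	1692	252	25.8	28	1.18
male	32	1541	1900	280	26.5	28.8	1.2
male	33	1724	2120	309	27.3	29.6	1.22
male	34	1913	2346	338	28	30.3	1.25
male	35	2106	2575	366	28.7	31.1	1.27
male	36	2300	2800	390	29.4	31.8	1.3
male	37	2491	3016	410	30	32.5	1.33
male	38	2671	3217	426	30.7	33.2	1.36
male	39	2835	3397	439	31.3	33.9	1.39
male	40	2973	3550	450	31.9	34.5	1.4
male	41	3080	3670	460	32.4	35	1.4
male	42	3148	3750	470	32.9	35.5	1.4
female	24	495	630	105	19.8	21.7	1
female	25	566	720	120	20.6	22.5	1.02
female	26	654	829	136	21.4	23.4	1.05
female	27	758	956	155	22.2	24.3	1.07
female	28	876	1100	175	23	25.1	1.1
female	29	1007	1259	196	23.8	25.9	1.13
female	30	1151	1432	219	24.6	26.8	1.15
female	31	1307	1619	244	25.4	27.6	1.18
female	32	1474	1820	270	26.1	28.4	1.2
female	33	1651	2033	298	26.9	29.2	1.22
female	34	1835	2253	326	27.6	30	1.25
female	35	2022	2474	352	28.3	30.7	1.27
female	36	2209	2690	375	29	31.4	1.3
female	37	2392	2896	393	29.6	32.1	1.33
female	38	2564	3086	408	30.2	32.7	1.36
female	39	2718	3256	420	30.7	33.3	1.39
female	40	2849	3400	430	31.3	33.9	1.4
female	41	2949	3513	440	31.8	34.4	1.4
female	42	3013	3590	450	32.3	34.9	1.4
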