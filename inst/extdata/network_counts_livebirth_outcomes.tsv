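site_id	livebirths	preterm	sga	microcephaly	neonatal_infection
st_josephs	1600	107	105	2	85
ejisu	1426	45	25	2	23
tema	5313	621	341	5	72
eastern	5238	710	247	2	52
mbeya_zrh	6855	508	116	1	71
st_francis	3373	368	NA	NA	74
mbeya_rrh	3837	222	119	3	97
mbare	5473	117	131	0	10
mutare	1469	406	119	0	7
mahdieh	5710	1177	249	30	64
shohada	836	113	17	8	61
castellon	1389	137	85	18	9
dr_peset	1078	56	60	14	7
jss	2760	386	124	9	62
grant_gmc	2151	382	45	0	17
ims_sum	1734	370	109	6	27
kasturba	2721	667	172	11	76
mp_shah	9808	830	181	9	88
skims	3136	379	37	1	34
patan	7468	887	126	3	282
bp_koirala	10333	580	818	15	141
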