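site_id	livebirths	neonatal_infection	invasive_bloodstream	meningitis	respiratory
st_josephs	1600	85	74	0	11
ejisu	1426	23	23	0	0
tema	5313	72	64	2	6
eastern	5238	52	49	3	0
mbeya_zrh	6855	71	67	2	2
st_francis	3373	74	66	4	4
mbeya_rrh	3837	97	93	2	2
mbare	5473	10	9	0	1
mutare	1469	7	6	0	1
mahdieh	5710	64	52	0	12
shohada	836	61	53	1	7
castellon	1389	9	7	1	1
dr_peset	1078	7	7	0	0
jss	2760	62	55	2	5
grant_gmc	2151	17	14	2	1
ims_sum	1734	27	24	3	0
kasturba	2721	76	71	3	2
mp_shah	9808	88	71	1	16
skims	3136	34	34	0	0
patan	7468	282	112	51	119
bp_koirala	10333	141	74	24	43
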