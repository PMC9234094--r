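site_id	country	facility_level	total_births	livebirths	stillbirth	neonatal_death	low_birthweight
st_josephs	Ghana	secondary	1632	1600	32	31	220
ejisu	Ghana	secondary	1441	1426	15	0	89
tema	Ghana	secondary	5523	5313	210	64	554
eastern	Ghana	secondary	5386	5238	148	103	753
mbeya_zrh	Tanzania	tertiary	7021	6855	166	124	682
st_francis	Tanzania	tertiary	3484	3373	111	71	431
mbeya_rrh	Tanzania	tertiary	3930	3837	93	61	321
mbare	Zimbabwe	primary	5500	5473	27	11	237
mutare	Zimbabwe	tertiary	1558	1469	89	88	484
mahdieh	Iran	tertiary	5802	5710	92	72	970
shohada	Iran	tertiary	862	836	26	16	82
castellon	Spain	tertiary	1390	1389	1	3	158
dr_peset	Spain	secondary	1078	1078	0	0	56
jss	India	tertiary	2786	2760	26	17	487
grant_gmc	India	tertiary	2247	2151	96	78	491
ims_sum	India	tertiary	1805	1734	71	7	445
kasturba	India	tertiary	2762	2721	41	30	708
mp_shah	India	tertiary	9971	9808	163	62	2421
skims	India	tertiary	3184	3136	48	32	299
patan	Nepal	tertiary	7555	7468	87	42	1064
bp_koirala	Nepal	tertiary	10554	10333	221	28	1327
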