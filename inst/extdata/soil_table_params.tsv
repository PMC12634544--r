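variable	unit	treatment	mean	sd
pH	unitless	B1	7.68	0.13
pH	unitless	B2	8.05	0.08
pH	unitless	B3	7.62	0.15
pH	unitless	B4	7.72	0.06
EC	uS/cm	B1	131.33	3.27
EC	uS/cm	B2	82.00	4.58
EC	uS/cm	B3	135.00	10.25
EC	uS/cm	B4	128.00	6.08
SOC	percent	B1	1.16	0.06
SOC	percent	B2	1.11	0.07
SOC	percent	B3	1.40	0.06
SOC	percent	B4	1.39	0.08
TN	percent	B1	0.13	0.01
TN	percent	B2	0.13	0.01
TN	percent	B3	0.16	0.01
TN	percent	B4	0.16	0.01
AP	mg/kg	B1	60.34	3.23
AP	mg/kg	B2	63.42	1.49
AP	mg/kg	B3	89.41	5.15
AP	mg/kg	B4	111.16	2.67
AK	mg/kg	B1	390.52	9.83
AK	mg/kg	B2	450.91	6.23
AK	mg/kg	B3	486.55	35.46
AK	mg/kg	B4	372.41	27.96
BG	umol/d/g	B1	62.74	4.72
BG	umol/d/g	B2	51.90	4.01
BG	umol/d/g	B3	44.87	3.38
BG	umol/d/g	B4	52.58	0.57
NAG	umol/d/g	B1	20.94	1.18
NAG	umol/d/g	B2	21.96	1.34
NAG	umol/d/g	B3	25.45	0.89
NAG	umol/d/g	B4	21.06	0.31
LAP	umol/d/g	B1	10.50	0.51
LAP	umol/d/g	B2	14.92	0.21
LAP	umol/d/g	B3	29.37	0.78
LAP	umol/d/g	B4	21.33	0.89
ALP	umol/d/g	B1	5.91	0.33
ALP	umol/d/g	B2	8.63	0.36
ALP	umol/d/g	B3	6.95	0.45
ALP	umol/d/g	B4	6.75	0.10
PPO	umol/d/g	B1	32.17	2.06
PPO	umol/d/g	B2	36.35	2.07
PPO	umol/d/g	B3	53.98	2.03
PPO	umol/d/g	B4	44.56	1.95
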