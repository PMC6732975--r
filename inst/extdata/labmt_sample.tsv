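word	rank	happiness_average	happiness_sd
love	1	8.42	1.11
happy	2	8.3	1.56
win	3	8.12	1.08
smile	4	8.1	1.02
won	5	8.1	1.22
music	6	8.02	1.12
weekend	7	8.0	1.18
celebrate	8	7.98	1.32
christmas	9	7.96	1.29
fun	10	7.96	1.31
free	11	7.96	1.26
great	12	7.88	1.13
success	13	7.86	1.12
positive	14	7.8	1.46
hero	15	7.8	1.24
birthday	16	7.78	1.26
family	17	7.72	1.39
super	18	7.68	1.22
amazing	19	7.66	1.31
forget	20	3.22	1.47
wrong	21	3.14	1.26
problem	22	2.98	1.28
lost	23	2.76	1.24
lose	24	2.76	1.28
bad	25	2.64	1.28
lie	26	2.6	1.39
stroke	27	2.58	1.47
aphasia	28	2.58	1.56
shit	29	2.5	1.66
shot	30	2.5	1.35
attack	31	2.42	1.35
sad	32	2.38	1.28
hate	33	2.34	1.45
poor	34	2.32	1.27
hell	35	2.22	1.62
pain	36	2.1	1.28
dead	37	2.0	1.32
fail	38	1.96	1.03
die	39	1.74	1.18
kill	40	1.56	1.05
death	41	1.54	1.28
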