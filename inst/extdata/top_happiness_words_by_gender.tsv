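word	gender	score	topic
love	Women	8.42	T16
happy	Women	8.3	T1
win	Women	8.12	T15
smile	Women	8.1	T1
won	Men	8.1	T17
music	Women	8.02	T2
weekend	Women	8.0	T3
celebrate	Women	7.98	T3
christmas	Women	7.96	T1
fun	Women	7.96	T3
free	Men	7.96	T11
great	Women	7.88	T3
success	Men	7.86	T10
award	Women	7.86	T15
positive	Women	7.8	T6
hero	Men	7.8	T10
sun	Men	7.8	T11
birthday	Women	7.78	T1
winner	Women	7.78	T15
beauty	Men	7.76	T5
family	Women	7.72	T6
gift	Women	7.72	T15
brilliant	Women	7.68	T2
super	Women	7.68	T6
amazing	Women	7.66	T16
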