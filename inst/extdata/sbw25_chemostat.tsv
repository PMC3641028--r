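strain	carbon_source	dilution_rate	od660	q_uptake	q_alginate	q_acetyl	q_co2	q_biomass_c	c_balance_printed
wild-type	fructose	0.04	7.8	9.4	0	0	7.5	1.51	95.7
mucA	fructose	0.04	7.0	18.3	12.3	0.77	4.6	1.51	104.4
dalgC	fructose	0.04	8.1	9.1	0	0	7.4	1.51	97.6
mucA_dalgC	fructose	0.04	8.4	5.8	0	0	4.3	1.51	99.3
mucA_TTalgD	fructose	0.04	9.2	5.6	0	0	3.9	1.51	96.9
wild-type	glycerol	0.04	9.2	8.3	0	0	6.4	1.51	96.3
mucA	glycerol	0.04	7.4	17.5	10.6	1.22	3.6	1.51	96.8
mucA_TTalgD	glycerol	0.04	9.9	6.9	0	0	5.0	1.51	95.4
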