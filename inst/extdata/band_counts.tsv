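genotype	replicate	n_I	n_II	n_III	n_IV
WT	1	1790	1994	813	841
WT	2	1802	2063	844	729
WT	3	1926	2092	840	580
NEG	1	1425	2538	846	629
NEG	2	1407	2525	887	619
NEG	3	1505	2519	860	554
POS	1	1346	2543	948	601
POS	2	1374	2587	878	599
POS	3	1503	2505	853	577
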