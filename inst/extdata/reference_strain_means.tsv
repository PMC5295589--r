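# Published second-fermentation trait means for the GN x SB cross:
# diploid parents (GN, SB), their haploid derivatives (hoGN, hoSB) and
# the diploid hybrid (HO-BN). Pressure traits in bar, rate in bar/day,
# threshold times in days (pressure expressed at 10 degrees C).
strain	Pmax	rate	t0.5	t2	t5
GN	5.33	0.53	4.00	8.60	26.00
SB	5.53	0.73	4.00	7.10	15.00
hoGN	5.50	0.61	5.00	9.00	28.00
hoSB	5.57	0.92	5.00	7.00	13.00
HO-BN	5.37	1.30	3.00	5.00	13.00
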