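location	host	n_samples	n_infected	n_strains
Rangtang	Elymus tangutorum	28	8	4
Rangtang	Elymus dahuricus	7	4	4
Hongyuan	Elymus cylindricus	44	36	6
Tumotezuo	Elymus sibiricus	12	2	2
Maqu	Elymus nutans	12	1	3
Huachi	Elymus dahuricus	6	4	1
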