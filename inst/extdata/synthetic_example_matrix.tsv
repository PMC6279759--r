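	Rosales	Malpighiales	Poales	Solanales	Brassicales
gen01	1	1	0	0	0
gen02	1	0	0	0	0
gen03	1	1	1	0	0
gen04	0	0	1	0	0
gen05	0	0	1	0	0
gen06	0	0	1	1	0
gen07	0	0	0	1	0
gen08	1	0	0	1	0
gen09	0	0	0	0	1
gen10	1	0	0	0	1
gen11	0	0	0	0	1
gen12	1	1	0	0	1
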