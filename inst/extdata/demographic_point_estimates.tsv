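parameter	point	lower	upper
N_anc	7826134	7652251	7962365
N_pop1	1882692	1863658	1891256
N_pop2	2663695	2651235	2678958
m12	3.97e-7	3.50e-7	4.15e-7
m21	9.19e-7	8.99e-7	9.98e-7
T_div_years	802365	793658	812546
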