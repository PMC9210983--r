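model	delta
1	3569618.436
2	3658352.526
3	2636451.235
4	0
5	2065856.026
6	216486.022
7	1868753.036
8	658541.035
9	1522688.015
10	1478223.020
11	4583631.025
12	2587456.015
13	5214852.061
14	136586.099
15	1253589.018
16	2659565.498
17	2568742.259
18	375961.568
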