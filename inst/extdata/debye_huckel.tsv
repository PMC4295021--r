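temperature_C	debye_A	debye_B	bdot
0	0.4913	0.3247	0.0394
10	0.4976	0.3261	0.0402
20	0.505	0.3276	0.0408
25	0.5092	0.3283	0.041
30	0.5141	0.3292	0.0414
40	0.5241	0.3307	0.0421
50	0.5351	0.3325	0.0427
60	0.5471	0.3343	0.0438
70	0.5599	0.3362	0.0445
80	0.5739	0.3382	0.0454
90	0.5891	0.3403	0.0458
100	0.6054	0.3425	0.046
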