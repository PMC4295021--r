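temperature_C	dgr0_kJ_mol
0	-44.2024
5	-44.9739
10	-45.7526
15	-46.5382
20	-47.3307
25	-48.13
30	-48.9359
35	-49.7484
40	-50.5672
45	-51.3924
50	-52.2239
55	-53.0614
60	-53.905
65	-54.7545
70	-55.6099
75	-56.4711
80	-57.3379
85	-58.2104
90	-59.0883
95	-59.9718
100	-60.8606
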