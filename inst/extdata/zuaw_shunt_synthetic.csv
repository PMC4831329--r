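frequency_hz,r_uaw,x_uaw
0.2,15,-994.706
0.5,15,-397.856
1,15,-198.881
2,15,-99.346
5,15,-39.475
8,15,-24.365
12,15,-15.825
16,15,-11.429
20,15,-8.691
24,15,-6.781
32,15,-4.206
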