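temperature_c,density_kg_per_L
0,0.99984
5,0.99997
10,0.99970
15,0.99910
20,0.99821
25,0.99705
30,0.99565
35,0.99403
40,0.99222
45,0.99022
50,0.98804
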