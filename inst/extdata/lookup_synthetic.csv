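thickness_nm,red,green,blue
0,157,157,157
10,160,161,163
20,168,172,179
30,180,187,199
40,194,204,219
50,208,220,236
60,222,234,249
70,234,245,255
80,244,252,255
90,251,255,248
100,255,254,235
110,255,249,217
120,254,239,197
130,248,226,176
140,240,210,160
150,229,193,154
160,215,176,160
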