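bin	dyad1	dyad2	dyad3	dyad4	dyad5
<0.1	318	286	273	272	276
0.1-0.15	6	24	26	23	33
0.15-0.2	0	11	18	19	11
0.2-0.25	0	3	4	6	4
0.25-0.3	0	0	3	2	0
>0.3	0	0	0	2	0
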