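exon	cds_width
1	120
2	120
3	120
4	120
5	120
6	120
7	120
8	120
9	120
10	120
11	120
12	120
13	120
14	120
15	120
16	120
17	120
18	120
19	120
20	120
21	123
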