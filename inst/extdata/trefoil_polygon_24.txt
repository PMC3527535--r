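24
1 2 -2 1
2 2 -1 1
3 2 0 1
4 2 0 0
5 1 0 0
6 0 0 0
7 0 -1 0
8 0 -2 0
9 0 -3 0
10 0 -3 1
11 0 -3 2
12 0 -2 2
13 0 -1 2
14 0 -1 1
15 1 -1 1
16 1 -1 0
17 1 -2 0
18 1 -2 -1
19 0 -2 -1
20 -1 -2 -1
21 -1 -2 0
22 -1 -2 1
23 0 -2 1
24 1 -2 1
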