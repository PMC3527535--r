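38
1 2 1 -1
2 2 1 0
3 1 1 0
4 0 1 0
5 -1 1 0
6 -1 1 -1
7 -1 0 -1
8 -1 -1 -1
9 -1 -1 0
10 0 -1 0
11 1 -1 0
12 1 -1 -1
13 1 0 -1
14 1 1 -1
15 0 1 -1
16 0 2 -1
17 -1 2 -1
18 -2 2 -1
19 -2 1 -1
20 -3 1 -1
21 -3 0 -1
22 -3 -1 -1
23 -2 -1 -1
24 -2 -2 -1
25 -1 -2 -1
26 0 -2 -1
27 0 -1 -1
28 0 0 -1
29 0 0 0
30 -1 0 0
31 -2 0 0
32 -2 0 -1
33 -2 0 -2
34 -1 0 -2
35 0 0 -2
36 1 0 -2
37 2 0 -2
38 2 1 -2
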