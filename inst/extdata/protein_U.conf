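40
1 1 1 0
2 1 2 0
3 1 2 1
4 1 2 2
5 1 2 3
6 1 1 3
7 1 0 3
8 1 0 2
9 0 0 2
10 0 0 1
11 1 0 1
12 1 0 0
13 0 0 0
14 0 1 0
15 0 2 0
16 0 2 1
17 0 1 1
18 0 1 2
19 1 1 2
20 1 1 1
21 2 1 1
22 2 1 2
23 2 1 3
24 2 0 3
25 2 0 4
26 2 1 4
27 1 1 4
28 1 0 4
29 0 0 4
30 0 0 3
31 0 1 3
32 0 2 3
33 0 2 4
34 1 2 4
35 2 2 4
36 2 2 3
37 2 2 2
38 2 2 1
39 2 2 0
40 2 1 0
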