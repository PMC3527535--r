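41
1 1 1 -1
2 1 1 0
3 1 1 1
4 1 2 1
5 1 2 2
6 1 2 3
7 1 1 3
8 1 0 3
9 0 0 3
10 0 0 2
11 0 0 1
12 1 0 1
13 1 0 0
14 2 0 0
15 2 1 0
16 2 2 0
17 1 2 0
18 0 2 0
19 0 2 1
20 0 2 2
21 0 1 2
22 1 1 2
23 1 0 2
24 2 0 2
25 2 0 3
26 2 1 3
27 2 1 4
28 1 1 4
29 1 0 4
30 0 0 4
31 0 1 4
32 0 1 3
33 0 2 3
34 0 2 4
35 1 2 4
36 2 2 4
37 2 2 3
38 2 2 2
39 2 1 2
40 2 1 1
41 2 2 1
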