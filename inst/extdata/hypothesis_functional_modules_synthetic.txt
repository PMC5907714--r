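# Synthetic reconstruction: functional modules (B F M N O OB)
# landmark module
1 O
2 O
3 N
4 N
5 N
6 N
7 M
8 M
9 M
10 M
11 N
12 OB
13 OB
14 OB
15 OB
16 OB
17 OB
18 OB
19 OB
20 M
21 M
22 M
23 M
24 F
25 F
26 M
27 M
28 M
29 M
30 B
31 B
32 F
33 F
34 F
35 F
36 F
37 O
38 O
39 O
40 M
41 M
42 M
43 M
44 O
45 O
46 O
47 M
48 M
49 B
50 B
51 B
52 M
53 M
54 B
55 B
56 B
57 B
58 B
59 B
60 B
61 B
62 B
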