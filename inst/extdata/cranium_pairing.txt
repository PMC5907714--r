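# Equid cranium bilateral pairing: landmark partner (0 = midline)
1 2
2 1
3 4
4 3
5 6
6 5
7 8
8 7
9 10
10 9
11 0
12 13
13 12
14 15
15 14
16 17
17 16
18 19
19 18
20 21
21 20
22 23
23 22
24 25
25 24
26 27
27 26
28 29
29 28
30 31
31 30
32 0
33 0
34 35
35 34
36 0
37 0
38 39
39 38
40 42
41 43
42 40
43 41
44 0
45 0
46 0
47 48
48 47
49 51
50 0
51 49
52 53
53 52
54 55
55 54
56 57
57 56
58 59
59 58
60 0
61 62
62 61
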