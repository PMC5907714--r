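# Equid mandible bilateral pairing: landmark partner (0 = midline)
1 0
2 3
3 2
4 5
5 4
6 0
7 8
8 7
9 10
10 9
11 12
12 11
13 14
14 13
15 16
16 15
17 18
18 17
19 20
20 19
21 22
22 21
23 24
24 23
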