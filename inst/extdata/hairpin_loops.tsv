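# Hairpin terminal-loop penalties, dg37 in kcal/mol at the 310.15 K reference.
# Tabulated sizes 3-30 (intermediate sizes linearly interpolated once, here);
# sizes > 30 extrapolated at run time with the Jacobson-Stockmayer term
# dg(n) = dg(30) + 1.75 * R * T * ln(n / 30).
# The loop term is treated as purely entropic, so dg(T) = dg37 * T / 310.15.
loop_size	dg37
3	3.5
4	3.5
5	3.3
6	4.0
7	4.2
8	4.3
9	4.5
10	4.6
11	4.8
12	5.0
13	5.05
14	5.1
15	5.2
16	5.3
17	5.4
18	5.5
19	5.6
20	5.7
21	5.78
22	5.86
23	5.94
24	6.02
25	6.1
26	6.14
27	6.18
28	6.22
29	6.26
30	6.3
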