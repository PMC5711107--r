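# flat unit objective profile (position_cm relative_dose)
-20 1
-19.5 1
-19 1
-18.5 1
-18 1
-17.5 1
-17 1
-16.5 1
-16 1
-15.5 1
-15 1
-14.5 1
-14 1
-13.5 1
-13 1
-12.5 1
-12 1
-11.5 1
-11 1
-10.5 1
-10 1
-9.5 1
-9 1
-8.5 1
-8 1
-7.5 1
-7 1
-6.5 1
-6 1
-5.5 1
-5 1
-4.5 1
-4 1
-3.5 1
-3 1
-2.5 1
-2 1
-1.5 1
-1 1
-0.5 1
0 1
0.5 1
1 1
1.5 1
2 1
2.5 1
3 1
3.5 1
4 1
4.5 1
5 1
5.5 1
6 1
6.5 1
7 1
7.5 1
8 1
8.5 1
9 1
9.5 1
10 1
10.5 1
11 1
11.5 1
12 1
12.5 1
13 1
13.5 1
14 1
14.5 1
15 1
15.5 1
16 1
16.5 1
17 1
17.5 1
18 1
18.5 1
19 1
19.5 1
20 1
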