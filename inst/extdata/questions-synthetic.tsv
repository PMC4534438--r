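index	short_label	text
1	Q1	Synthetic placeholder text for questionnaire item 1 (parent-reported respiratory symptom item; real wording not distributed with this package)
2	Q2	Synthetic placeholder text for questionnaire item 2 (parent-reported respiratory symptom item; real wording not distributed with this package)
3	Q3	Synthetic placeholder text for questionnaire item 3 (parent-reported respiratory symptom item; real wording not distributed with this package)
4	Q4	Synthetic placeholder text for questionnaire item 4 (parent-reported respiratory symptom item; real wording not distributed with this package)
5	Q5	Synthetic placeholder text for questionnaire item 5 (parent-reported respiratory symptom item; real wording not distributed with this package)
6	Q6	Synthetic placeholder text for questionnaire item 6 (parent-reported respiratory symptom item; real wording not distributed with this package)
7	Q7	Synthetic placeholder text for questionnaire item 7 (parent-reported respiratory symptom item; real wording not distributed with this package)
8	Q8	Synthetic placeholder text for questionnaire item 8 (parent-reported respiratory symptom item; real wording not distributed with this package)
9	Q9	Synthetic placeholder text for questionnaire item 9 (parent-reported respiratory symptom item; real wording not distributed with this package)
10	Q10	Synthetic placeholder text for questionnaire item 10 (parent-reported respiratory symptom item; real wording not distributed with this package)
11	Q11	Synthetic placeholder text for questionnaire item 11 (parent-reported respiratory symptom item; real wording not distributed with this package)
12	Q12	Synthetic placeholder text for questionnaire item 12 (parent-reported respiratory symptom item; real wording not distributed with this package)
13	Q13	Synthetic placeholder text for questionnaire item 13 (parent-reported respiratory symptom item; real wording not distributed with this package)
14	Q14	Synthetic placeholder text for questionnaire item 14 (parent-reported respiratory symptom item; real wording not distributed with this package)
15	Q15	Synthetic placeholder text for questionnaire item 15 (parent-reported respiratory symptom item; real wording not distributed with this package)
16	Q16	Synthetic placeholder text for questionnaire item 16 (parent-reported respiratory symptom item; real wording not distributed with this package)
17	Q17	Synthetic placeholder text for questionnaire item 17 (parent-reported respiratory symptom item; real wording not distributed with this package)
18	Q18	Synthetic placeholder text for questionnaire item 18 (parent-reported respiratory symptom item; real wording not distributed with this package)
19	Q19	Synthetic placeholder text for questionnaire item 19 (parent-reported respiratory symptom item; real wording not distributed with this package)
20	Q20	Synthetic placeholder text for questionnaire item 20 (parent-reported respiratory symptom item; real wording not distributed with this package)
21	Q21	Synthetic placeholder text for questionnaire item 21 (parent-reported respiratory symptom item; real wording not distributed with this package)
22	Q22	Synthetic placeholder text for questionnaire item 22 (parent-reported respiratory symptom item; real wording not distributed with this package)
23	Q23	Synthetic placeholder text for questionnaire item 23 (parent-reported respiratory symptom item; real wording not distributed with this package)
24	Q24	Synthetic placeholder text for questionnaire item 24 (parent-reported respiratory symptom item; real wording not distributed with this package)
25	Q25	Synthetic placeholder text for questionnaire item 25 (parent-reported respiratory symptom item; real wording not distributed with this package)
26	Q26	Synthetic placeholder text for questionnaire item 26 (parent-reported respiratory symptom item; real wording not distributed with this package)
27	Q27	Synthetic placeholder text for questionnaire item 27 (parent-reported respiratory symptom item; real wording not distributed with this package)
28	Q28	Synthetic placeholder text for questionnaire item 28 (parent-reported respiratory symptom item; real wording not distributed with this package)
29	Q29	Synthetic placeholder text for questionnaire item 29 (parent-reported respiratory symptom item; real wording not distributed with this package)
30	Q30	Synthetic placeholder text for questionnaire item 30 (parent-reported respiratory symptom item; real wording not distributed with this package)
31	Q31	Synthetic placeholder text for questionnaire item 31 (parent-reported respiratory symptom item; real wording not distributed with this package)
32	Q32	Synthetic placeholder text for questionnaire item 32 (parent-reported respiratory symptom item; real wording not distributed with this package)
33	Q33	Synthetic placeholder text for questionnaire item 33 (parent-reported respiratory symptom item; real wording not distributed with this package)
34	Q34	Synthetic placeholder text for questionnaire item 34 (parent-reported respiratory symptom item; real wording not distributed with this package)
35	Q35	Synthetic placeholder text for questionnaire item 35 (parent-reported respiratory symptom item; real wording not distributed with this package)
36	Q36	Synthetic placeholder text for questionnaire item 36 (parent-reported respiratory symptom item; real wording not distributed with this package)
37	Q37	Synthetic placeholder text for questionnaire item 37 (parent-reported respiratory symptom item; real wording not distributed with this package)
38	Q38	Synthetic placeholder text for questionnaire item 38 (parent-reported respiratory symptom item; real wording not distributed with this package)
39	Q39	Synthetic placeholder text for questionnaire item 39 (parent-reported respiratory symptom item; real wording not distributed with this package)
40	Q40	Synthetic placeholder text for questionnaire item 40 (parent-reported respiratory symptom item; real wording not distributed with this package)
41	Q41	Synthetic placeholder text for questionnaire item 41 (parent-reported respiratory symptom item; real wording not distributed with this package)
42	Q42	Synthetic placeholder text for questionnaire item 42 (parent-reported respiratory symptom item; real wording not distributed with this package)
43	Q43	Synthetic placeholder text for questionnaire item 43 (parent-reported respiratory symptom item; real wording not distributed with this package)
44	Q44	Synthetic placeholder text for questionnaire item 44 (parent-reported respiratory symptom item; real wording not distributed with this package)
45	Q45	Synthetic placeholder text for questionnaire item 45 (parent-reported respiratory symptom item; real wording not distributed with this package)
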