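donor_id	gender	age	sample_id	disc_level	mri_grade	compartment	ivd_total	ivd_any_zero	dd_total	dd_any_two
1	m	55	1	C4/5	4	AF	10	FALSE	0	FALSE
1	m	55	1	C4/5	4	NP	9	FALSE	1	FALSE
1	m	55	2	C5/6	4	AF	9	FALSE	1	FALSE
1	m	55	2	C5/6	4	NP	7	FALSE	4	TRUE
2	f	43	3	C4/5	3	AF	10	FALSE	2	FALSE
2	f	43	3	C4/5	3	NP	7	FALSE	1	FALSE
2	f	43	4	C5/6	3	AF	5	TRUE	3	TRUE
2	f	43	4	C5/6	3	NP	9	FALSE	2	FALSE
2	f	43	5	C6/7	3	AF	10	FALSE	3	TRUE
2	f	43	5	C6/7	3	NP	7	FALSE	2	TRUE
3	m	59	6	C4/5	3	AF	6	TRUE	1	FALSE
3	m	59	6	C4/5	3	NP	4	TRUE	4	TRUE
3	m	59	7	C5/6	3	AF	7	FALSE	2	FALSE
3	m	59	7	C5/6	3	NP	3	TRUE	4	TRUE
3	m	59	8	C6/7	3	AF	9	FALSE	1	FALSE
3	m	59	8	C6/7	3	NP	4	TRUE	3	FALSE
4	f	45	9	C5/6	3	AF	11	FALSE	2	FALSE
4	f	45	9	C5/6	3	NP	9	FALSE	2	FALSE
5	m	62	10	C3/4	4	AF	2	TRUE	3	TRUE
5	m	62	10	C3/4	4	NP	8	FALSE	2	FALSE
5	m	62	11	C4/5	4	AF	5	TRUE	1	FALSE
5	m	62	11	C4/5	4	NP	6	FALSE	2	FALSE
6	f	76	12	C4/5	3	AF	10	FALSE	0	FALSE
6	f	76	12	C4/5	3	NP	6	TRUE	3	FALSE
7	m	36	13	C4/5	4	AF	8	FALSE	1	FALSE
7	m	36	13	C4/5	4	NP	11	FALSE	1	FALSE
7	m	36	14	C5/6	4	AF	7	TRUE	3	TRUE
7	m	36	14	C5/6	4	NP	9	TRUE	3	TRUE
7	m	36	15	C6/7	4	AF	9	FALSE	3	FALSE
7	m	36	15	C6/7	4	NP	9	FALSE	2	FALSE
8	m	45	16	C3/4	4	AF	7	FALSE	4	TRUE
8	m	45	16	C3/4	4	NP	7	FALSE	3	TRUE
9	f	76	17	C4/5	4	AF	6	TRUE	4	TRUE
9	f	76	17	C4/5	4	NP	7	FALSE	4	TRUE
10	f	42	18	C5/6	4	AF	9	TRUE	4	TRUE
10	f	42	18	C5/6	4	NP	7	FALSE	4	TRUE
10	f	42	19	C6/7	3	AF	7	TRUE	2	FALSE
10	f	42	19	C6/7	3	NP	7	TRUE	2	FALSE
11	m	55	20	C4/5	4	AF	2	TRUE	2	FALSE
11	m	55	20	C4/5	4	NP	6	TRUE	1	FALSE
11	m	55	21	C5/6	4	AF	8	FALSE	2	FALSE
11	m	55	21	C5/6	4	NP	7	FALSE	2	FALSE
12	f	64	22	C3/4	4	AF	11	FALSE	2	FALSE
12	f	64	22	C3/4	4	NP	5	TRUE	2	FALSE
13	f	77	23	C6/7	4	AF	4	TRUE	3	TRUE
13	f	77	23	C6/7	4	NP	6	TRUE	3	TRUE
14	m	47	24	C5/6	4	AF	9	FALSE	2	FALSE
14	m	47	24	C5/6	4	NP	5	TRUE	1	FALSE
15	f	46	25	C4/5	4	AF	1	TRUE	1	FALSE
15	f	46	25	C4/5	4	NP	7	FALSE	2	FALSE
16	m	59	26	C5/6	4	AF	9	FALSE	1	FALSE
16	m	59	26	C5/6	4	NP	5	TRUE	3	TRUE
16	m	59	27	C6/7	3	AF	8	FALSE	2	FALSE
16	m	59	27	C6/7	3	NP	9	FALSE	2	FALSE
17	f	46	28	C5/6	3	AF	9	FALSE	2	FALSE
17	f	46	28	C5/6	3	NP	7	FALSE	1	FALSE
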