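table	row	group	mean	sd	n
1	age	A	26.85	5.88	38
1	age	B	26.71	7.62	62
1	production_time	A	1.15	1.02	38
1	production_time	B	1.09	1.01	62
1	gestational_weeks	A	31.25	2.15	38
1	gestational_weeks	B	31.16	2.37	62
3	nbna	A	34.45	4.25	38
3	nbna	B	33.65	4.72	62
3	nse_birth	A	26.28	7.21	38
3	nse_birth	B	27.11	7.42	62
3	nse_day3	A	33.22	9.58	38
3	nse_day3	B	32.16	10.05	62
4	body_mass	A	2721.42	241.15	38
4	body_mass	B	2511.72	203.36	62
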