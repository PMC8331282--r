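table	row	statistic	printed	annotated
1	age	t	0.103	TRUE
1	production_time	t	0.287	FALSE
1	gestational_weeks	t	0.191	FALSE
3	nbna	t	0.854	FALSE
3	nse_birth	t	0.549	FALSE
3	nse_day3	t	0.521	FALSE
4	body_mass	t	4.661	FALSE
1	twins	chi2	0.059	FALSE
3	hie	chi2	0.131	FALSE
4	perinatal_death	chi2	1.648	FALSE
4	rds	chi2	0.075	FALSE
5	maternal_complications	chi2	6.579	FALSE
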