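# Published concentration-mortality summaries for the susceptible and
# resistant Brazilian Aedes aegypti strains (larvae: ug a.i./mL; adults:
# ug a.i./cm2). `source` distinguishes the tabulated values from the
# adult permethrin susceptible LC50 quoted in the running text, which
# differs from the tabulated one and is the value consistent with the
# published resistance ratio of 102.2.
stage	insecticide	strain	n	slope	slope_se	lc50	lc50_lo	lc50_hi	chi2	p_value	source
larvae	permethrin	susceptible	600	16.2	5.05	1.1e-3	9.8e-4	1.5e-3	7.07	0.13	table
larvae	permethrin	resistant	500	1.7	0.15	64.7	46.31	89.54	0.30	0.95	table
larvae	deltamethrin	susceptible	420	4.4	0.56	2.7e-3	2.2e-3	3.3e-3	1.92	0.59	table
larvae	deltamethrin	resistant	420	0.7	0.13	4.4	2.94	6.18	6.23	0.18	table
adults	permethrin	susceptible	591	2.6	0.28	4.3e-3	4.0e-3	4.5e-3	5.04	0.17	table
adults	permethrin	susceptible	591	2.6	0.28	3.4e-3	3.0e-3	3.8e-3	5.04	0.17	text
adults	permethrin	resistant	809	4.0	0.27	0.35	0.32	0.38	6.51	0.55	table
adults	deltamethrin	susceptible	671	5.3	0.39	7.6e-6	6.6e-6	8.8e-6	5.67	0.23	table
adults	deltamethrin	resistant	562	1.8	0.13	9.8e-4	8.2e-4	1.2e-3	2.62	0.60	table
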