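variable	case_mean	case_sd	case_n	control_mean	control_sd	control_n	transform	reported_p
maternal_age_years	27.18	5.33	76	26.02	5.32	43	none	0.256
gestational_age_weeks	30.05	4.17	76	38.93	1.16	43	none	<0.001
neonatal_weight_kg	1.69	1.59	76	3.14	0.46	43	none	<0.001
gravidity	3.53	2.04	76	3.25	2.57	43	sqrt	0.555
parity	1.47	1.57	76	1.35	1.41	43	sqrt	0.657
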