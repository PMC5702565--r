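key	value
wes_n_cases	76
wes_n_controls	43
followup_n_cases	188
followup_n_controls	175
combined_n_cases	264
combined_n_controls	218
fut2_hom_cases	16
fut2_hom_controls	4
fut2_hom_case_pct	21
fut2_hom_control_pct	9.3
burden_empirical_p	0.0416
burden_n_perm	10000
n_case_higher	10
n_digenic	7
detection_freq	0.005
detection_n_chrom	304
detection_power_pct	78
aims_n_markers	102
aims_delta	0.733
theta_mean_cases	0.695
theta_sd_cases	0.073
theta_mean_controls	0.698
theta_sd_controls	0.087
defb1_case_carriers	6
card6_case_carriers	2
mbl2_case_carriers	6
fut2_rs143482452_case_carriers	1
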