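# Example cohort configuration; any subset of these keys may be given.
# Values shown are the package defaults.
ldl_target: 2.5            # mmol/L, on target means strictly below
low_ldl_cutoff: 0.8        # mmol/L, unreliable before remeasure_date
high_tg_cutoff: 8.0        # mmol/L, Friedewald panels above are excluded
remeasure_date: 2017-01-24
cvd_window_days: 7
egfr_window_days: 2
egfr_ckd_threshold: 60
short_min_days: 61
short_max_days: 183
long_max_days: 548
truncation_percentile: 75
transitions_on_truncated: false
n_clusters: 4
indel_cost: 1.0
substitution_method: constant
substitution_constant: 2.0
bp_window_days: 7
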