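# Bundled calibrated scenarios, v1.
#
# Published per-million-adult summary values for six indirect pandemic
# health conditions and their mitigation strategies. Money cells are in
# millions of 2020 USD unless the field name says otherwise; QALY cells are
# absolute per million adults. Long-term cells are present-value (already
# discounted at 3% over a 10-year mean lag). Per-episode parameters and
# baseline prevalences are re-derived from these summaries at load time
# (see backsolve_condition / calibrate_intervention); baselines are
# illustrative, not authoritative.
version: 1
defaults:
  discount_rate: 0.03
  long_term_lag_years: 10
  coverage: 0.20
  n_adults: 1000000
scenarios:
  depression:
    condition_label: "Depressive symptoms"
    intervention_label: "Cognitive-behavioral therapy + antidepressants"
    rr: 1.37
    rr_low: 1.20
    rr_high: 2.56
    cost_per_episode: 32599
    excess_qalys_short: 24831
    excess_qalys_long: 43807
    excess_cost_short_m: 954
    excess_cost_long_m: 1277
    qalys_gained: 12707
    intervention_cost_m: 44.5
    net1_m: 61.5
    net3_m: 161.7
    net10_m: 241.5
    provenance: "published summary tables, depressive-symptoms rows"
  ipv:
    condition_label: "Intimate partner violence"
    intervention_label: "Nurse-family partnership"
    rr: 1.11
    rr_low: 1.05
    rr_high: 1.16
    cost_per_episode: 115562
    excess_qalys_short: 2445
    excess_qalys_long: 49902
    excess_cost_short_m: 373
    excess_cost_long_m: 326
    qalys_gained: 22186
    intervention_cost_m: 164.7
    net1_m: -69.8
    net3_m: 5.3
    net10_m: 54.6
    provenance: "published summary tables, intimate-partner-violence rows"
  homelessness:
    condition_label: "Homelessness"
    intervention_label: "Rent subsidies"
    rr: 6.67
    rr_low: 5.34
    rr_high: 8.00
    cost_per_episode: 99969
    # pandemic-era homelessness is modeled as acute (stays with
    # friends/family), with health-outcome values reduced 75%
    severity_multiplier: 0.25
    excess_qalys_short: 12951
    excess_qalys_long: 3527
    excess_cost_short_m: 706
    excess_cost_long_m: 1448
    qalys_gained: 1648
    intervention_cost_m: 47.1
    net1_m: -4.7
    net3_m: 45.4
    net10_m: 92.4
    provenance: "published summary tables, homelessness rows"
  alcohol:
    condition_label: "Excessive alcohol use"
    intervention_label: "Screening and brief intervention"
    rr: 1.19
    rr_low: 1.07
    rr_high: 1.42
    cost_per_episode: 94004
    excess_qalys_short: 5928
    excess_qalys_long: 19807
    excess_cost_short_m: 138
    excess_cost_long_m: 952
    qalys_gained: 4835
    intervention_cost_m: 6.6
    net1_m: 8.9
    net3_m: 52.5
    net10_m: 107.4
    provenance: "published summary tables, excessive-alcohol-use rows"
  oud:
    condition_label: "Opioid use disorder"
    intervention_label: "Medication-assisted treatment"
    rr: 1.63
    rr_low: 1.33
    rr_high: 1.98
    cost_per_episode: 79551
    excess_qalys_short: 3239
    excess_qalys_long: 24877
    excess_cost_short_m: 166
    excess_cost_long_m: 385
    qalys_gained: 5674
    intervention_cost_m: 56.2
    net1_m: -36.0
    net3_m: -10.5
    net10_m: 14.5
    provenance: "published summary tables, opioid-use-disorder rows"
  stroke:
    condition_label: "Stroke mortality"
    intervention_label: "Public awareness campaign"
    rr: 1.53
    rr_low: 1.40
    rr_high: 1.67
    cost_per_episode: 16773
    # campaign reaches 100% of those at risk of in-hospital stroke
    # mortality; no long-term component (published long-term cells empty)
    coverage: 1.0
    excess_qalys_short: 1214
    excess_qalys_long: 0
    excess_cost_short_m: 0.844
    excess_cost_long_m: 0
    qalys_gained: 388
    intervention_cost_m: 0.01435
    net1_m: 0.1475
    net3_m: 0.2285
    net10_m: 0.242
    provenance: "published summary tables, stroke-mortality rows"
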