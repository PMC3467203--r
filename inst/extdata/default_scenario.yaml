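start_age: 65.0
cycle_days: 14.0
horizon_years: 35.0
wtp: 50000.0
fatal_ech_fraction: 0.0
fatal_mi_fraction: 0.0
stroke_mort_composition: replace
utility_combination: multiplicative
half_cycle: no
parameters:
  cost_warfarin_2wk:
  - 18.0
  - 3.0
  - 28.0
  cost_apixaban_2wk:
  - 95.0
  - 51.0
  - 154.0
  cost_aspirin_2wk:
  - 0.3
  - 0.07
  - 2.8
  cost_event_rind:
  - 6562.0
  - 3500.0
  - 13000.0
  cost_event_minor_stroke:
  - 9956.0
  - 4500.0
  - 18000.0
  cost_event_major_stroke:
  - 14783.0
  - 11000.0
  - 27500.0
  cost_biweekly_minor_stroke:
  - 1232.0
  - 500.0
  - 2000.0
  cost_biweekly_major_stroke:
  - 2683.0
  - 1000.0
  - 4500.0
  cost_event_ich:
  - 41645.0
  - 16500.0
  - 71000.0
  cost_biweekly_ich:
  - 2835.0
  - 1000.0
  - 4500.0
  cost_biweekly_stroke_ich:
  - 3595.0
  - 1600.0
  - 7000.0
  cost_event_ech:
  - 5830.0
  - 2000.0
  - 9000.0
  cost_event_minor_bleed:
  - 42.0
  - 0.0
  - 200.0
  cost_event_mi:
  - 20357.0
  - 16500.0
  - 24000.0
  cost_biweekly_mi:
  - 152.0
  - 69.0
  - 300.0
  cost_nonevent_death:
  - 5000.0
  - 0.0
  - 10000.0
  disc_rate_pct:
  - 3.0
  - 0.0
  - 5.0
  u_warfarin:
  - 0.987
  - 0.94
  - 1.0
  u_apixaban:
  - 0.994
  - 0.975
  - 1.0
  u_aspirin:
  - 0.998
  - 0.994
  - 1.0
  u_major_neuro:
  - 0.39
  - 0.0
  - 1.0
  u_minor_neuro:
  - 0.75
  - 0.0
  - 1.0
  du_major_bleed:
  - -0.16
  - -0.3
  - 0.0
  du_minor_bleed:
  - -0.16
  - -0.3
  - 0.0
  u_mi:
  - 0.84
  - 0.5
  - 1.0
  rate_stroke_warfarin:
  - 1.05
  - 0.92
  - 1.24
  hr_stroke_apixaban:
  - 1.0
  - 0.74
  - 1.13
  rr_stroke_aspirin:
  - 2.08
  - 1.59
  - 2.7
  rr_stroke_decade:
  - 1.4
  - ~
  - ~
  frac_stroke_fatal:
  - 8.2
  - 8.2
  - 10.1
  frac_stroke_major:
  - 40.2
  - 40.2
  - 41.7
  frac_stroke_minor:
  - 42.5
  - 34.8
  - 42.5
  frac_stroke_rind:
  - 9.1
  - 9.1
  - 13.3
  frac_stroke_asp_fatal:
  - 17.9
  - 10.1
  - 17.9
  frac_stroke_asp_major:
  - 30.0
  - 30.0
  - 41.1
  frac_stroke_asp_minor:
  - 41.0
  - 34.8
  - 41.0
  frac_stroke_asp_rind:
  - 11.0
  - 11.0
  - 13.3
  rate_ich_warfarin:
  - 0.8
  - 0.63
  - 0.89
  hr_ich_apixaban:
  - 0.42
  - 0.3
  - 0.58
  rr_ich_decade:
  - 1.97
  - ~
  - ~
  frac_ich_fatal:
  - 36.4
  - 28.3
  - 45.2
  frac_ich_major:
  - 14.1
  - 9.0
  - 21.4
  frac_ich_minor:
  - 49.5
  - ~
  - ~
  rate_ech_warfarin:
  - 3.09
  - 2.59
  - 3.16
  hr_ech_apixaban:
  - 0.69
  - 0.6
  - 0.8
  rate_minor_bleed_warfarin:
  - 2.55
  - 2.32
  - 2.8
  rr_minor_bleed_apixaban:
  - 0.69
  - 0.59
  - 0.8
  rr_hemorrhage_aspirin:
  - 0.87
  - 0.59
  - 0.9
  rate_mi_warfarin:
  - 0.61
  - 0.51
  - 0.76
  hr_mi_apixaban:
  - 1.0
  - 0.66
  - 1.17
  rr_mi_aspirin:
  - 1.42
  - 0.84
  - 2.39
  rr_mi_decade:
  - 1.3
  - ~
  - ~
  rr_death_af:
  - 1.3
  - 1.12
  - 1.62
  rr_death_af_stroke:
  - 2.3
  - 1.3
  - 3.0
  tia_fraction_pct:
  - 28.0
  - ~
  - ~
life_table: bundled
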