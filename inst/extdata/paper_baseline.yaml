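settings:
  cycle_length_days: 21.0
  discount_rate_annual: 0.03
  horizon_mode: fixed_cycles
  mortality_fraction_threshold: 0.99
  max_cycles: 139
  half_cycle_correction: no
  pd_cost_mode: bsc
  pfs_death_rule: os_competing
  os_median_calibration: scale
  hfs_scope: alive
  hepatectomy_branch_cycle: 4
  wtp_thresholds:
    China: 30492.0
    Beijing: 72000.0
    Fujian: 47285.0
    Gansu: 14595.0
  currency_rate_cny_per_usd: 6.77
  costs_currency: USD
  random_seed: 20190101
costs:
  per_cycle:
    sorafenib: 2308.32
    oxaliplatin: 273.31
    fluorouracil: 514.65
    leucovorin: 23.74
    haic_procedure: 1817.03
    hospitalization: 376.92
    test: 352.19
    bsc: 357.0
    hfs: 11.54
  one_time:
    hepatectomy: 8862.629999999999
    elevated_alt_ast: 42.54
    neutropenia: 82.39
    diarrhea: 5.66
    nausea_vomiting: 48.35
  bsa_reference: 1.72
  bsa_patient: 1.72
utilities:
  pfs: 0.76
  pd: 0.68
  disutility:
    elevated_alt_ast: 0.0
    neutropenia: 0.09
    hfs: 0.016
    diarrhea: 0.047
    nausea_vomiting: 0.048
recurrence:
  crs_score: 1
  cumulative_incidence: 0.335
  horizon_years: 5.0
mortality:
  flat_annual_probability: 0.00713
strategies:
  sorahaic:
    name: SoraHAIC
    uses_haic: yes
    pfs_weibull:
      scale: 0.0985
      shape: 0.97
    os_weibull:
      scale: 0.02858
      shape: 1.39235
    os_target_median_months: 13.37
    hepatectomy_fraction: 0.128
    sae_incidence:
      elevated_alt_ast: 0.4
      neutropenia: 0.097
      hfs: 0.1
      diarrhea: 0.089
      nausea_vomiting: 0.14
    subsequent_mix:
      sorafenib: 0.3
      haic: 0.29
      bsc: 0.41
  sorafenib:
    name: Sorafenib
    uses_haic: no
    pfs_weibull:
      scale: 0.17
      shape: 1.295
    os_weibull:
      scale: 0.06
      shape: 1.48
    os_target_median_months: 7.13
    hepatectomy_fraction: 0.0082
    sae_incidence:
      elevated_alt_ast: 0.34
      neutropenia: 0.025
      hfs: 0.14
      diarrhea: 0.12
      nausea_vomiting: 0.025
    subsequent_mix:
      sorafenib: 0.346534653465
      haic: 0.326732673267
      bsc: 0.326732673267
ranges:
  utility_pfs:
    min: 0.61
    max: 0.91
    dist: beta
  utility_pd:
    min: 0.54
    max: 0.82
    dist: beta
  cost_sorafenib:
    min: 1846.66
    max: 2769.98
    dist: gamma
  cost_oxaliplatin:
    min: 218.65
    max: 327.97
    dist: gamma
  cost_fluorouracil:
    min: 411.72
    max: 617.58
    dist: gamma
  cost_leucovorin:
    min: 18.99
    max: 28.49
    dist: gamma
  cost_haic_procedure:
    min: 1453.62
    max: 2180.44
    dist: gamma
  cost_hepatectomy:
    min: 7090.1
    max: 10635.16
    dist: gamma
  cost_hospitalization:
    min: 301.54
    max: 452.3
    dist: gamma
  cost_test:
    min: 281.75
    max: 422.63
    dist: gamma
  cost_bsc:
    min: 167.64
    max: 847.84
    dist: gamma
  cost_sae_elevated_alt_ast:
    min: 33.04
    max: 49.56
    dist: gamma
  cost_sae_neutropenia:
    min: 65.91
    max: 98.87
    dist: gamma
  cost_sae_hfs:
    min: 9.23
    max: 11.54
    dist: gamma
  cost_sae_diarrhea:
    min: 4.53
    max: 6.79
    dist: gamma
  cost_sae_nausea_vomiting:
    min: 38.68
    max: 58.02
    dist: gamma
  disutility_neutropenia:
    min: 0.059
    max: 0.12
    dist: beta
  disutility_hfs:
    min: 0.013
    max: 0.019
    dist: beta
  disutility_diarrhea:
    min: 0.016
    max: 0.077
    dist: beta
  disutility_nausea_vomiting:
    min: 0.038
    max: 0.058
    dist: beta
  inc_sorahaic_elevated_alt_ast:
    min: 0.32
    max: 0.48
    dist: beta
  inc_sorahaic_neutropenia:
    min: 0.077
    max: 0.12
    dist: beta
  inc_sorahaic_hfs:
    min: 0.084
    max: 0.13
    dist: beta
  inc_sorahaic_diarrhea:
    min: 0.071
    max: 0.11
    dist: beta
  inc_sorahaic_nausea_vomiting:
    min: 0.11
    max: 0.16
    dist: beta
  inc_sorafenib_elevated_alt_ast:
    min: 0.27
    max: 0.41
    dist: beta
  inc_sorafenib_neutropenia:
    min: 0.02
    max: 0.03
    dist: beta
  inc_sorafenib_hfs:
    min: 0.11
    max: 0.17
    dist: beta
  inc_sorafenib_diarrhea:
    min: 0.099
    max: 0.15
    dist: beta
  inc_sorafenib_nausea_vomiting:
    min: 0.02
    max: 0.03
    dist: beta
  hepatectomy_sorahaic:
    min: 0.1
    max: 0.15
    dist: beta
  hepatectomy_sorafenib:
    min: 0.0066
    max: 0.0098
    dist: beta
  mix_sorahaic_sorafenib:
    min: 0.24
    max: 0.36
    dist: beta
  mix_sorahaic_haic:
    min: 0.23
    max: 0.35
    dist: beta
  mix_sorahaic_bsc:
    min: 0.33
    max: 0.49
    dist: beta
  mix_sorafenib_sorafenib:
    min: 0.28
    max: 0.42
    dist: beta
  mix_sorafenib_haic:
    min: 0.26
    max: 0.39
    dist: beta
  mix_sorafenib_bsc:
    min: 0.26
    max: 0.39
    dist: beta
  bsa:
    min: 1.38
    max: 2.06
    dist: normal
  recurrence_rate:
    min: 0.313
    max: 0.341
    dist: beta
  discount_rate:
    min: 0.0
    max: 0.05
    dist: fixed

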