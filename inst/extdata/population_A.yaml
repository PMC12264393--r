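cuckoo:
  role: cuckoo
  lifespan_max: 10
  lifespan_mean: 7.5
  eggs_max: 8
  eggs_mean: 5.0
  n_initial: 360
  n_partner_species: 2
  weibull_shape: 3.0
  weibull_scale: 12.255344504689
  prob_means:
    lay_success: 0.65
    mimic_color: 0.15
    mimic_shape: 0.15
    mimic_vocal: 0.2
    fertility: 0.75
  prob_sds:
    lay_success: 0.0065
    mimic_color: 0.0015
    mimic_shape: 0.0015
    mimic_vocal: 0.002
    fertility: 0.0075
  reinforcement:
    lay_success: 0.0065
host:
  role: host
  lifespan_max: 4
  lifespan_mean: 3.0
  eggs_max: 7
  eggs_mean: 4.2
  n_initial: 360
  n_partner_species: 1
  weibull_shape: 3.0
  weibull_scale: 3.962590065236
  prob_means:
    nest_guard: 0.3
    detect_color: 0.4
    detect_shape: 0.4
    detect_vocal: 0.3
    fertility: 0.75
    rearing: 0.75
  prob_sds:
    nest_guard: 0.003
    detect_color: 0.004
    detect_shape: 0.004
    detect_vocal: 0.003
    fertility: 0.0075
    rearing: 0.0075
  reinforcement:
    nest_guard: 0.003
    detect_color: 0.004
    detect_shape: 0.004
    detect_vocal: 0.003
    rearing: 0.0075
  capacity: 450
n_host_species: 2
backup: yes
renest_max: 1
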