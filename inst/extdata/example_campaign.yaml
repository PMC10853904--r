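# Example campaign configuration: lamivudine-style targets and bounds with a
# synthetic virtual-lab ground truth whose relations all cross their targets
# at supersaturation 2.4 and 25 degC.
targets:
  t_ind_s: 3600
  r_nuc_per_s: 0.1
  r_growth_um_s: 0.01
  growth_weight: 10
bounds:
  ss_min: 2
  ss_max: 3
  t_min: 5
  t_max: 50
center:
  ss: 2.4
  temp_C: 20
truth:
  rate_noise_cv: 0.2
  relations:
    - parameter: induction_time
      variable: supersaturation
      A: 1
      a: -3
      b: 15.388661
    - parameter: nucleation_rate
      variable: supersaturation
      a: 0.15
      b: -0.26
    - parameter: growth_rate
      variable: supersaturation
      a: 0.008
      b: -0.0092
    - parameter: nucleation_rate
      variable: temperature
      A: 1
      a: 0.1
      b: -4.802585
    - parameter: growth_rate
      variable: temperature
      a: 0.0004
      b: 0.0
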