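# Cohort presets: printed summary statistics of the source cohorts, used as
# calibration constraints for the truncated-normal-mixture surrogates.
# Onset offsets (ADD - EDD) are in days relative to the EDD; latent-phase
# durations are in hours.
khambalia:
  kind: onset
  target_mean: -1.48
  target_sd: 9.21
  interval: [-7.0, 7.0]
  interval_mass: 0.66
  support: [-30.0, 30.0]
  n_components: 2
  default_n: 10243
mongelli:
  kind: onset
  target_mean: -1.79
  target_sd: 11.3
  support: [-30.0, 30.0]
  n_components: 1
  default_n: 34249
friedman_nulliparous:
  kind: latent
  parity: nulliparous
  target_mean: 7.1
  target_sd: 4.0
  quantile_prob: 0.95
  quantile_value: 20.0
  support: [0.0, 30.0]
  n_components: 2
  default_n: 500
friedman_multiparous:
  kind: latent
  parity: multiparous
  target_mean: 5.3
  target_sd: 4.1
  quantile_prob: 0.95
  quantile_value: 14.0
  support: [0.0, 16.0]
  n_components: 2
  default_n: 500
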