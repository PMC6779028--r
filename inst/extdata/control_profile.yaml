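# Default non-CTS (control) impairment profile.
# Per direction: [median, ci_lo, ci_hi] of the published group medians.
# max_speed / avg_speed in cm/s, total_time in s. Log-normal dispersion is
# back-fitted so the 2.5th/97.5th population quantiles roughly span the
# printed intervals (an approximation: the printed intervals are 95% CIs of
# the median, not population quantiles).
label: non-CTS
miss_prob: 0.05
reaction_time:
  median_s: 0.25
  sigma_log: 0.2
directions:
  - {direction: 0,  max_speed: [11.18, 7.79, 21.89], avg_speed: [7.22, 4.96, 12.16],  total_time: [0.53, 0.33, 0.90]}
  - {direction: 1,  max_speed: [12.42, 9.45, 20.22], avg_speed: [7.75, 4.87, 10.80],  total_time: [0.57, 0.38, 0.93]}
  - {direction: 2,  max_speed: [10.97, 7.30, 17.37], avg_speed: [6.14, 4.91, 9.58],   total_time: [0.50, 0.40, 0.88]}
  - {direction: 3,  max_speed: [11.29, 8.35, 15.64], avg_speed: [7.48, 4.33, 10.70],  total_time: [0.47, 0.37, 1.00]}
  - {direction: 4,  max_speed: [12.47, 9.21, 16.00], avg_speed: [6.98, 4.46, 9.53],   total_time: [0.47, 0.38, 0.58]}
  - {direction: 5,  max_speed: [14.24, 8.98, 22.14], avg_speed: [13.48, 5.78, 15.25], total_time: [0.32, 0.23, 0.50]}
  - {direction: 6,  max_speed: [12.63, 6.82, 16.12], avg_speed: [7.53, 5.80, 12.01],  total_time: [0.48, 0.35, 0.58]}
  - {direction: 7,  max_speed: [10.75, 6.07, 19.30], avg_speed: [6.82, 5.02, 14.53],  total_time: [0.45, 0.27, 0.65]}
  - {direction: 8,  max_speed: [8.80, 7.39, 16.78],  avg_speed: [6.67, 4.81, 13.13],  total_time: [0.55, 0.25, 0.80]}
  - {direction: 9,  max_speed: [10.42, 6.47, 15.53], avg_speed: [7.18, 4.83, 10.18],  total_time: [0.63, 0.40, 0.73]}
  - {direction: 10, max_speed: [10.70, 8.01, 13.76], avg_speed: [7.64, 5.57, 11.16],  total_time: [0.52, 0.32, 0.75]}
  - {direction: 11, max_speed: [10.81, 6.68, 16.67], avg_speed: [8.54, 4.27, 12.02],  total_time: [0.37, 0.30, 0.82]}
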