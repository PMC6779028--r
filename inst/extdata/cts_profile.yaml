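# Default CTS impairment profile; see control_profile.yaml for the format.
label: CTS
miss_prob: 0.05
reaction_time:
  median_s: 0.30
  sigma_log: 0.2
directions:
  - {direction: 0,  max_speed: [9.97, 8.56, 14.52],  avg_speed: [5.20, 4.32, 6.60], total_time: [0.77, 0.58, 0.97]}
  - {direction: 1,  max_speed: [9.32, 7.73, 12.11],  avg_speed: [5.57, 4.52, 8.62], total_time: [0.85, 0.63, 1.10]}
  - {direction: 2,  max_speed: [10.05, 8.37, 13.65], avg_speed: [4.77, 3.70, 7.48], total_time: [0.80, 0.68, 1.10]}
  - {direction: 3,  max_speed: [8.68, 7.45, 13.19],  avg_speed: [5.59, 3.20, 6.59], total_time: [0.72, 0.55, 1.30]}
  - {direction: 4,  max_speed: [10.54, 8.89, 14.99], avg_speed: [6.10, 3.44, 7.56], total_time: [0.63, 0.57, 1.07]}
  - {direction: 5,  max_speed: [10.96, 8.71, 14.19], avg_speed: [6.71, 3.41, 7.82], total_time: [0.75, 0.50, 1.18]}
  - {direction: 6,  max_speed: [10.59, 7.94, 12.73], avg_speed: [4.90, 2.99, 6.38], total_time: [0.75, 0.60, 1.40]}
  - {direction: 7,  max_speed: [8.71, 6.40, 12.62],  avg_speed: [5.41, 3.37, 6.42], total_time: [0.55, 0.45, 0.95]}
  - {direction: 8,  max_speed: [11.74, 6.90, 15.52], avg_speed: [4.95, 3.48, 6.71], total_time: [0.58, 0.40, 1.08]}
  - {direction: 9,  max_speed: [10.82, 6.03, 12.85], avg_speed: [6.06, 3.57, 7.63], total_time: [0.63, 0.58, 0.92]}
  - {direction: 10, max_speed: [9.50, 6.02, 11.90],  avg_speed: [4.76, 3.09, 7.16], total_time: [0.70, 0.43, 0.95]}
  - {direction: 11, max_speed: [9.18, 7.17, 12.10],  avg_speed: [4.32, 3.13, 5.73], total_time: [0.65, 0.43, 1.12]}
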