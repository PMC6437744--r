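subject,r_overall_mean,r_overall_sd,r_individual_mean,r_individual_sd,r_streamlined_individual,r_streamlined_baseline
1,0.86,0.04,0.92,0.05,0.90,0.88
2,0.35,0.18,0.85,0.10,0.68,0.23
3,0.69,0.07,0.78,0.10,0.84,0.69
4,0.76,0.16,0.84,0.10,0.93,0.90
5,0.24,0.29,0.69,0.15,0.87,0.05
6,0.47,0.12,0.88,0.05,0.83,0.52
7,0.40,0.20,0.61,0.15,0.66,0.74
8,0.74,0.16,0.87,0.11,0.95,0.83
9,0.74,0.08,0.94,0.06,0.96,0.85
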