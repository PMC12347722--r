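cutoff,sensitivity,specificity
112.70,1.000,0.000
122.48,1.000,0.053
139.00,1.000,0.105
155.40,1.000,0.158
167.44,1.000,0.263
177.76,0.923,0.263
188.91,0.846,0.263
195.29,0.846,0.316
199.58,0.846,0.368
204.64,0.846,0.421
208.26,0.846,0.474
214.89,0.846,0.526
221.54,0.769,0.526
228.32,0.769,0.579
238.96,0.769,0.684
262.72,0.769,0.737
283.50,0.769,0.787
286.84,0.692,0.789
297.79,0.615,0.789
335.73,0.538,0.842
368.14,0.462,0.842
381.51,0.462,0.895
397.00,0.385,0.895
408.88,0.308,0.895
434.57,0.231,0.895
467.30,0.154,0.470
610.79,0.154,1.000
822.14,0.077,1.000
904.04,0.000,1.000
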