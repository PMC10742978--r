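age_category,n,nolla_mean_error,nolla_mae,demirjian_mean_error,demirjian_mae,atlas_mean_error,atlas_mae
4,7,0.58,0.58,2.02,2.02,0.44,0.56
5,26,0.49,0.72,1.86,1.86,0.36,0.49
6,18,0.63,0.67,1.57,1.57,0.43,0.67
7,18,0.13,0.65,1.33,1.33,0.65,1.00
8,14,0.09,0.89,1.91,1.92,0.48,1.27
9,16,-0.35,0.82,1.57,1.71,0.72,1.05
10,20,0.00,1.23,1.94,1.94,0.97,1.29
11,20,0.59,1.61,1.57,1.58,0.82,0.87
12,19,-0.19,0.88,1.19,1.41,0.12,0.89
13,20,0.38,1.02,1.59,1.59,0.71,0.82
14,21,0.34,1.09,1.56,1.62,0.48,0.85
15,20,0.03,1.03,1.28,1.36,0.36,1.14
16,20,-0.74,1.23,1.73,2.09,0.63,1.27
17,24,-0.89,0.89,1.45,2.16,0.30,1.75
18,21,-1.37,1.37,3.11,3.39,1.25,1.67
19,20,-2.42,2.42,2.02,2.57,0.63,1.70
20,20,-3.55,3.55,0.54,2.49,-0.30,2.08
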