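age_category,nolla_1y,nolla_2y,demirjian_1y,demirjian_2y,atlas_1y,atlas_2y
4,71.43,100.00,0.00,57.14,85.71,100.00
5,73.08,100.00,0.00,50.00,76.92,96.15
6,83.33,100.00,5.56,88.89,66.67,100.00
7,77.78,100.00,33.33,94.44,61.11,83.33
8,50.00,100.00,21.43,50.00,35.71,85.71
9,62.50,93.75,25.00,62.50,56.25,81.25
10,52.63,89.47,15.79,68.42,47.37,84.21
11,20.00,75.00,35.00,65.00,70.00,90.00
12,52.63,94.74,47.37,73.68,57.89,100.00
13,45.00,90.00,30.00,55.00,75.00,90.00
14,52.38,85.71,42.86,66.67,61.90,95.24
15,45.00,95.00,50.00,85.00,65.00,85.00
16,66.67,71.43,42.86,47.62,57.14,76.19
17,62.50,91.67,41.67,66.67,37.50,75.00
18,0.00,95.24,4.76,14.29,47.62,76.19
19,0.00,0.00,15.00,20.00,45.00,70.00
20,0.00,0.00,0.00,25.00,35.00,50.00
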