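participant,mass_kg,measured_mlkgmin,measured_lmin,estimated_mlkgmin,estimated_lmin,difference
1,75,9.15,0.69,9.33,0.71,-0.18
2,74.25,7.67,0.81,8.27,0.78,-0.60
3,73,9.26,0.68,9.19,0.70,0.07
4,85,8.24,0.96,8.63,0.91,-0.39
5,77.70,5.95,0.88,7.09,0.83,-1.13
6,75,9.35,0.84,9.33,0.80,0.02
7,63,12.80,0.62,11.67,0.62,1.13
8,93,8.53,0.82,8.70,0.86,-0.17
9,81,8.90,0.89,9.02,0.85,-0.12
10,70,11.98,0.67,10.94,0.68,1.04
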