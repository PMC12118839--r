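depth,gross_mean,gross_se,bioerosion_mean,bioerosion_se,net_mean,net_se,accretion_mean,accretion_se,n_transects
2,4.84,0.61,-5.19,0.86,0.17,0.97,0.17,1.04,30
3,5.67,0.67,-8.31,1.63,-2.11,1.89,-2.20,2.76,30
6,7.03,0.87,-5.16,0.76,2.40,1.36,2.29,1.25,30
9,3.65,0.42,-2.93,0.48,1.25,0.68,1.22,0.71,30
17,2.85,0.57,-2.39,0.75,0.99,1.00,0.97,1.13,30
overall,4.81,0.31,-4.80,0.46,0.54,0.57,0.53,0.70,150
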