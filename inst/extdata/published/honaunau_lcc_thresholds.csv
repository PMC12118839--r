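depth,threshold_lcc,ci_lower,ci_upper,lcc_surveyed_mean,lcc_surveyed_se
2,23.70,5.05,51.45,23.23,2.77
3,39.39,13.30,72.07,28.16,3.23
6,19.76,2.99,47.32,31.16,4.06
9,27.65,7.47,55.57,34.65,3.47
17,20.79,4.02,48.35,25.11,4.43
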