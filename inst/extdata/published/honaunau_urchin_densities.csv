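depth,diadematidae_mean,diadematidae_se,echinometra_mean,echinometra_se,other_eroding_mean,other_eroding_se,tripneustes_mean,tripneustes_se
2,0.87,0.22,15.13,1.65,0.30,0.10,0.10,0.10
3,1.17,0.28,12.17,1.23,0.90,0.19,0.10,0.06
6,0.40,0.12,15.57,1.52,2.07,0.39,0.20,0.09
9,0.17,0.08,10.37,1.01,1.07,0.41,0.50,0.16
17,0.33,0.10,1.73,0.54,0.27,0.11,0.23,0.09
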