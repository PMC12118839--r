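group,per_quadrat_mean,per_quadrat_se,density_per_m2
all_species,12.73,0.75,51
excluding_echinometra,1.73,0.16,7
echinometra_only,10.99,0.69,44
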