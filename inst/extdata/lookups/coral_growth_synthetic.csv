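taxon,level,kind,value,source
Porites lobata,species,porites_depth_model,NA,depth-dependent linear/exponential model
Porites compressa,species,porites_depth_model,NA,depth-dependent linear/exponential model
Porites evermanni,species,porites_depth_model,NA,depth-dependent linear/exponential model
Montipora capitata,species,fixed,1.10,synthetic default (cm y-1)
Montipora patula,species,fixed,0.80,synthetic default (cm y-1)
Montipora flabellata,species,fixed,0.75,synthetic default (cm y-1)
Pocillopora meandrina,species,fixed,2.00,synthetic default (cm y-1)
Pocillopora grandis,species,fixed,2.30,synthetic default (cm y-1)
Pavona varians,species,fixed,0.47,synthetic default (cm y-1)
Pavona duerdeni,species,fixed,0.60,synthetic default (cm y-1)
Leptastrea purpurea,species,fixed,0.40,synthetic default (cm y-1)
Fungia scutaria,species,fixed,0.90,synthetic default (cm y-1)
Porites,genus,porites_depth_model,NA,depth-dependent linear/exponential model
Montipora,genus,fixed,0.90,synthetic default (cm y-1)
Pocillopora,genus,fixed,2.10,synthetic default (cm y-1)
Pavona,genus,fixed,0.54,synthetic default (cm y-1)
Leptastrea,genus,fixed,0.40,synthetic default (cm y-1)
default,default,fixed,1.00,synthetic default (cm y-1)
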