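taxon,level,value,source
Porites lobata,species,1.0,synthetic default (massive)
Porites compressa,species,0.6,synthetic default (branching)
Porites evermanni,species,1.0,synthetic default (massive)
Montipora capitata,species,0.8,synthetic default (plating/encrusting)
Montipora patula,species,1.0,synthetic default (encrusting)
Montipora flabellata,species,1.0,synthetic default (encrusting)
Pocillopora meandrina,species,0.6,synthetic default (branching)
Pocillopora grandis,species,0.6,synthetic default (branching)
Pavona varians,species,1.0,synthetic default (encrusting)
Pavona duerdeni,species,1.0,synthetic default (massive)
Leptastrea purpurea,species,1.0,synthetic default (encrusting)
Fungia scutaria,species,1.0,synthetic default (free-living)
Porites,genus,1.0,synthetic default (massive)
Montipora,genus,1.0,synthetic default (encrusting)
Pocillopora,genus,0.6,synthetic default (branching)
Pavona,genus,1.0,synthetic default (encrusting)
Leptastrea,genus,1.0,synthetic default (encrusting)
default,default,1.0,synthetic default (unadjusted)
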