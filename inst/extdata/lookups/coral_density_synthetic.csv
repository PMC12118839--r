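taxon,level,value,source
Porites lobata,species,1.41,synthetic default (g cm-3)
Porites compressa,species,1.29,synthetic default (g cm-3)
Porites evermanni,species,1.38,synthetic default (g cm-3)
Montipora capitata,species,1.65,synthetic default (g cm-3)
Montipora patula,species,1.72,synthetic default (g cm-3)
Montipora flabellata,species,1.70,synthetic default (g cm-3)
Pocillopora meandrina,species,1.72,synthetic default (g cm-3)
Pocillopora grandis,species,1.70,synthetic default (g cm-3)
Pavona varians,species,1.47,synthetic default (g cm-3)
Pavona duerdeni,species,1.50,synthetic default (g cm-3)
Leptastrea purpurea,species,2.00,synthetic default (g cm-3)
Fungia scutaria,species,1.56,synthetic default (g cm-3)
Porites,genus,1.36,synthetic default (g cm-3)
Montipora,genus,1.69,synthetic default (g cm-3)
Pocillopora,genus,1.71,synthetic default (g cm-3)
Pavona,genus,1.49,synthetic default (g cm-3)
Leptastrea,genus,2.00,synthetic default (g cm-3)
default,default,1.55,synthetic default (g cm-3)
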