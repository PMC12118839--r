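species,brc,source
Chlorurus spilurus,2.80,synthetic default
Scarus psittacus,3.10,synthetic default
Scarus rubroviolaceus,1.80,synthetic default
Scarus dubius,2.50,synthetic default
Calotomus carolinus,1.50,synthetic default
default,2.30,synthetic default (sister-species fallback)
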