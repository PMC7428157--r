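component,amount,unit,ph,oxygen_mmol_per_l,aqueous
tryptone,10,g/L,7,18.2,TRUE
yeast_extract,5,g/L,,,
nacl,10,g/L,,,
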