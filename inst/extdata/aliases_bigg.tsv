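compound	alias_of	relationship
ncam	nac	nicotinamide carried by the nicotinate exchange
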