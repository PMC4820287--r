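site,type1,type2,type3
GHS,295,16,388
Aurora,0,7,249
Mayo,72,0,106
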