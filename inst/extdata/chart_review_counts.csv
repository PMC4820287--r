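site,cases_reviewed,cases_confirmed,controls_reviewed,controls_confirmed,emerge
GHS,50,47,50,50,TRUE
Mayo,50,44,50,50,TRUE
Marshfield,25,25,22,22,TRUE
Aurora,50,48,50,50,FALSE
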