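gene,list
NXF1,proteomics
WDR77,proteomics
COPS3,proteomics
CEP152,proteomics
GPS1,proteomics
NXF1,rnai
GPS1,rnai
MYD88,rnai
TLR7,rnai
RIPK2,rnai
IKBKG,rnai
DHX58,rnai
ENPP7,rnai
MAP4K1,rnai
PSMA1,rnai
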