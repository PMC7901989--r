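# Iron minerals: Fe(III)/Fe(II) atoms per formula unit.
name,formula,fe3_per_unit,fe2_per_unit
HFO,Fe(OH)3,1,0
goethite,FeO(OH),1,0
hematite,Fe2O3,2,0
magnetite,Fe3O4,2,1
Fe-NTA,FeC6H6NO6,1,0
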