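# UK TTO (MVH A1) value-set decrements for the EQ-5D-3L.
# utility = 1 - constant*[any dimension > 1] - sum(level decrements) - n3*[any dimension at 3]
# term: "constant", "n3", or <dimension>_<level> with dimensions
# MO (mobility), SC (self-care), UA (usual activities), PD (pain/discomfort),
# AD (anxiety/depression) and levels 2, 3.
term,decrement
constant,0.081
MO_2,0.069
MO_3,0.314
SC_2,0.104
SC_3,0.214
UA_2,0.036
UA_3,0.094
PD_2,0.123
PD_3,0.386
AD_2,0.071
AD_3,0.236
n3,0.269
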