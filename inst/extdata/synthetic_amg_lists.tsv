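identifier	list
K00001	known
K00002	known
K00003	known
K00399	known
GH13	known
K00001	verified
K00399	verified
GH5	attachment
C26	peptidase
PF00665	transposon
K07497	transposon
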