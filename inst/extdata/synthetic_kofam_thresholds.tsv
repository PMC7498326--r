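model_id	threshold	score_type
K00001	100.00	full
K00002	75.50	domain
K00003	220.10	full
K00399	150.00	full
K00010		full
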