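module_id	name	definition	block
M90001	mock glycolysis	K00001 K00002 K00003	pathway
M90002	mock branched pathway	(K00001,K00004) K00002	pathway
M90003	mock salvage pathway	K00010 (K00001 K00002),(K00003)	pathway
C90001	mock dehydrogenase complex	K10944+K10945+K10946	complex
C90002	mock reductase complex	(K00001,K00002)+K00399 K00010	complex
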