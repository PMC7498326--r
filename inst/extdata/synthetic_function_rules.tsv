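function_name	category	subcategory	required_sets
methanogenesis_mcrA	energy	methanogenesis	K00399
ammonia_oxidation	energy	nitrification	K10944;K10945,K10946
starch_utilization	carbon utilization	starch degradation	GH13
glycolysis_entry	energy	glycolysis	K00001,K00002
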