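identifier	description	category	subcategory
K00001	hexokinase	energy	glycolysis
K00002	alcohol dehydrogenase	energy	fermentation
K00003	homoserine dehydrogenase	organic nitrogen	amino acid synthesis
K00010	inositol transport system	transporters	sugar transport
K00399	methyl-coenzyme M reductase alpha subunit	energy	methanogenesis
GH13	alpha-amylase family	carbon utilization	starch degradation
GH13	alpha-amylase family	carbon utilization	glycogen degradation
GH5	cellulase family	carbon utilization	cellulose degradation
PF00001	7 transmembrane receptor	MISC	signal transduction
C26	gamma-glutamyl hydrolase	organic nitrogen	peptidases
K10944	ammonia monooxygenase subunit A	energy	nitrification
K10945	ammonia monooxygenase subunit B	energy	nitrification
K10946	ammonia monooxygenase subunit C	energy	nitrification
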