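class	dichotomy	category	count	printed_percent
LM_unique	chromosomal	intrachromosomal	614	37.9
LM_unique	chromosomal	interchromosomal	1003	62.1
LM_unique	coding	coding	1245	76.9
LM_unique	coding	noncoding	372	23.1
LM_unique	frame	in_frame	136	8.5
LM_unique	frame	out_of_frame	1481	91.5
pCRC_unique	chromosomal	intrachromosomal	838	56.1
pCRC_unique	chromosomal	interchromosomal	658	43.9
pCRC_unique	coding	coding	1137	76
pCRC_unique	coding	noncoding	359	24
pCRC_unique	frame	in_frame	47	3.1
pCRC_unique	frame	out_of_frame	1449	96.9
common	chromosomal	intrachromosomal	74	79.5
common	chromosomal	interchromosomal	19	20.5
common	coding	coding	73	78.5
common	coding	noncoding	20	21.5
common	frame	in_frame	5	5.3
common	frame	out_of_frame	88	94.7
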