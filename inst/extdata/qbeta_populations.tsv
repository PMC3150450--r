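population_id	generation	lineages
NCBI		
Anc	0	1,2,3,4
M54	54	1,2
M109	109	1
M163	163	1
M165_2	165	2
S94_3	94	3
S169_3	169	3
S168_4	168	4
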