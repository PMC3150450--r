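genome_position	ancestral_nt	evolved_nt	NCBI	Anc	M54	M109	M163	M165_2	S94_3	S169_3	S168_4
47	G	A									±
52	A	G				±	+			±	±
66	U	A						±			
221	U	G			+	±		±			
519	A	G				±	±	±			
569	G	A	+	±	+	+	+	+	+	+	+
789	C	U						±			
830	U	C				±	+	±			
1257	C	U	+				±				
1288	A	G					±	±			
1344	A	G						±			
1371	G	C						+			
1795	U	C					±				
2249	C	U	+		+	+	+	+	+	+	+
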