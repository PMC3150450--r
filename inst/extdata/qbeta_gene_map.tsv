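name	start	end	genome_length
A2	61	1323	4217
coat	1344	1742	4217
A1	1344	2333	4217
replicase	2352	4118	4217
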