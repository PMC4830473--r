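doc_id	level	kind	wild	position	mutant	rs_id	multiplicity	surfaces	source
doc1	dna	SNP				rs121434569	1	rs121434569	toolB
doc1	dna	SUB	G	5557	A		1		
doc2	protein	SUB	T	790	M		2	T790M;Thr790Met	toolA
doc3	protein	DEL	E	746			1	E746del	
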