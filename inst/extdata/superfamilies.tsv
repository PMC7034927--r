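family	superfamily
tRNA	tRNA
rRNA_5S	rRNA
rRNA_5_8S	rRNA
snoRNA_CD	snoRNA
snoRNA_HACA	snoRNA
miRNA	miRNA
lncRNA	lncRNA
antisense	antisense
histone	histone
snRNA	snRNA
riboswitch	riboswitch
ribozyme	ribozyme
IRES	IRES
leader	leader
frameshift	frameshift
CRISPR	CRISPR
tRNA_sec	tRNA
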