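codon	anticodon	tgcn	s
TTT	AAA	1	0
TTT	AAA	3	0.41
TTC	GAA	6	0
TTA	TAA	4	0
TTG	CAA	5	0
TCT	AGA	0	0
TCC	GGA	4	0
TCC	GGA	3	0.28
TCA	TGA	2	0
TCA	TGA	3	0.41
TCG	CGA	1	0
TAT	ATA	3	0
TAT	ATA	4	0.28
TAC	GTA	4	0
TAC	GTA	1	0.68
TGT	ACA	6	0
TGT	ACA	0	0.41
TGC	GCA	2	0
TGC	GCA	0	0.41
TGG	CCA	2	0
TGG	CCA	3	0.41
CTT	AAG	3	0
CTC	GAG	5	0
CTC	GAG	3	0.41
CTA	TAG	6	0
CTG	CAG	5	0
CCT	AGG	3	0
CCT	AGG	0	0.28
CCC	GGG	6	0
CCA	TGG	2	0
CCG	CGG	6	0
CCG	CGG	2	0.68
CAT	ATG	2	0
CAC	GTG	1	0
CAA	TTG	0	0
CAA	TTG	1	0.41
CAG	CTG	4	0
CAG	CTG	2	0.68
CGT	ACG	4	0
CGT	ACG	1	0.28
CGC	GCG	0	0
CGC	GCG	5	0.41
CGA	TCG	6	0
CGA	TCG	3	0.68
CGG	CCG	0	0
ATT	AAT	0	0
ATC	GAT	3	0
ATA	TAT	0	0
ATA	TAT	0	0.68
ATG	CAT	3	0
ACT	AGT	5	0
ACC	GGT	3	0
ACA	TGT	5	0
ACG	CGT	4	0
AAT	ATT	3	0
AAT	ATT	4	0.28
AAC	GTT	6	0
AAC	GTT	6	0.41
AAA	TTT	4	0
AAG	CTT	5	0
AAG	CTT	6	0.28
AGT	ACT	3	0
AGC	GCT	4	0
AGC	GCT	1	0.28
AGA	TCT	1	0
AGA	TCT	3	0.68
AGG	CCT	6	0
AGG	CCT	4	0.68
GTT	AAC	2	0
GTC	GAC	0	0
GTA	TAC	1	0
GTA	TAC	2	0.68
GTG	CAC	6	0
GTG	CAC	3	0.41
GCT	AGC	4	0
GCT	AGC	3	0.41
GCC	GGC	3	0
GCA	TGC	5	0
GCA	TGC	1	0.28
GCG	CGC	1	0
GCG	CGC	1	0.68
GAT	ATC	0	0
GAC	GTC	4	0
GAA	TTC	5	0
GAG	CTC	0	0
GAG	CTC	2	0.41
GGT	ACC	6	0
GGC	GCC	2	0
GGC	GCC	5	0.41
GGA	TCC	2	0
GGA	TCC	6	0.28
GGG	CCC	0	0
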