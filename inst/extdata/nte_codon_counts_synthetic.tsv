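codon	gene01	gene02	gene03	gene04	gene05	gene06	gene07	gene08	gene09	gene10	gene11	gene12	gene13	gene14	gene15	gene16	gene17	gene18	gene19	gene20
TTT	5	5	5	3	4	8	9	5	4	6	3	6	4	3	5	6	2	4	5	3
TTC	5	7	6	2	3	1	5	11	3	6	9	9	5	5	6	5	3	4	7	5
TTA	5	4	3	8	8	5	6	5	8	9	6	3	10	8	5	7	9	4	5	5
TTG	2	4	4	8	5	8	5	5	5	7	4	5	13	5	6	10	7	7	5	3
TCT	6	5	8	6	7	7	11	7	9	9	4	3	3	9	3	6	5	6	4	4
TCC	11	5	3	4	6	7	6	10	5	9	4	6	2	3	7	3	8	5	8	5
TCA	7	5	6	5	4	7	9	7	5	2	7	6	5	11	7	6	4	5	7	3
TCG	6	3	4	8	10	4	7	5	5	8	8	7	9	7	3	7	8	6	6	5
TAT	7	5	5	7	7	5	7	9	9	9	5	3	6	9	9	9	7	8	3	9
TAC	4	8	5	7	3	6	7	4	4	5	8	7	8	7	4	13	5	5	3	7
TGT	3	7	6	5	6	4	8	7	5	5	6	4	3	8	6	8	5	4	5	4
TGC	7	3	9	5	7	5	8	5	2	3	8	10	6	4	6	5	9	9	4	4
TGG	3	4	5	7	6	6	5	9	10	7	4	7	2	9	3	3	5	7	4	8
CTT	7	7	10	4	5	8	10	4	8	5	5	6	2	6	5	6	3	7	7	6
CTC	5	6	3	4	5	6	4	6	8	8	2	2	6	5	7	7	7	3	10	5
CTA	7	5	4	11	6	8	7	6	7	8	6	5	5	4	7	5	6	4	3	6
CTG	8	5	6	9	4	8	10	6	5	7	7	7	9	5	3	4	6	10	6	7
CCT	4	6	5	7	8	3	4	5	9	6	7	6	7	5	5	3	8	5	5	5
CCC	6	5	3	8	10	9	9	9	4	5	10	6	7	3	3	5	6	9	2	8
CCA	11	11	2	9	5	8	3	9	4	5	3	9	5	7	6	9	5	7	4	11
CCG	5	5	4	4	5	5	5	4	7	13	6	4	7	5	2	3	7	5	7	6
CAT	3	4	5	5	9	3	3	7	7	7	4	5	6	4	9	8	6	9	7	5
CAC	6	10	10	7	5	5	6	6	5	9	2	5	5	9	5	8	4	7	5	3
CAA	4	8	5	3	8	8	7	6	8	4	6	7	12	9	4	6	7	5	5	5
CAG	3	9	4	3	4	3	5	3	4	4	5	4	7	5	4	2	6	7	7	7
CGT	5	6	4	6	8	4	9	8	8	5	3	7	3	3	5	9	5	8	8	3
CGC	4	8	8	8	5	3	4	3	9	5	10	4	8	5	6	6	4	6	6	9
CGA	7	5	7	14	5	2	5	9	5	4	8	1	7	7	7	4	3	5	6	7
CGG	7	5	10	5	3	11	6	5	2	5	6	6	7	4	9	7	7	3	3	7
ATT	5	3	5	3	4	6	6	6	4	10	6	6	5	8	5	8	4	6	3	4
ATC	5	4	3	4	3	7	3	7	3	3	3	10	4	6	8	3	4	7	5	5
ATA	6	5	9	5	2	8	3	8	8	6	10	3	6	4	6	5	2	6	5	8
ATG	6	8	8	5	6	9	4	5	6	4	2	5	5	7	2	4	4	4	7	4
ACT	8	5	3	2	9	8	5	7	6	6	11	12	5	10	7	6	7	5	7	6
ACC	4	9	7	7	3	5	7	7	3	8	5	9	7	1	3	5	7	3	8	3
ACA	6	4	5	1	3	3	9	6	7	8	5	8	6	5	5	3	7	5	14	6
ACG	7	9	9	11	8	8	6	7	11	3	4	6	6	4	8	7	4	4	4	4
AAT	5	6	9	4	8	2	6	4	9	5	10	2	7	7	3	5	6	6	4	12
AAC	4	11	10	3	5	8	7	5	5	6	9	9	7	3	6	5	5	10	11	10
AAA	8	7	4	3	4	5	6	5	6	6	4	7	5	8	9	6	7	6	7	8
AAG	6	3	8	2	4	10	7	10	5	10	4	7	8	4	6	15	4	7	3	2
AGT	8	6	4	3	5	6	7	6	6	7	7	6	6	5	7	8	9	4	3	9
AGC	9	3	6	4	6	8	6	8	4	5	7	4	2	9	7	3	5	7	4	5
AGA	8	4	6	10	6	2	6	6	7	7	4	7	4	3	2	7	5	11	8	6
AGG	1	8	7	3	4	5	4	6	7	1	5	8	6	6	6	11	6	8	7	4
GTT	5	4	4	5	7	7	6	5	11	9	9	8	8	9	9	10	8	8	9	3
GTC	3	7	3	2	8	6	2	6	7	2	6	6	6	6	4	7	6	7	6	7
GTA	8	6	5	6	7	3	5	2	8	3	5	4	8	3	8	7	9	6	5	4
GTG	4	5	3	7	6	10	6	8	9	12	7	9	7	5	7	5	4	3	6	5
GCT	7	6	3	8	4	7	7	11	8	8	8	8	4	5	6	3	9	5	4	6
GCC	11	10	6	4	8	4	12	7	8	6	8	10	5	5	8	5	4	10	5	5
GCA	8	7	4	6	5	4	5	5	6	6	8	3	6	6	8	8	8	6	1	6
GCG	8	5	11	3	6	6	3	7	5	6	7	5	9	7	5	8	6	12	6	9
GAT	3	6	3	3	5	8	8	3	12	6	7	9	9	2	4	7	6	8	8	4
GAC	5	5	6	7	4	7	8	6	5	6	7	5	6	4	6	4	8	4	5	8
GAA	5	2	9	8	5	7	6	7	6	6	6	4	7	7	5	7	2	5	5	6
GAG	7	7	5	6	3	11	3	9	6	6	7	8	4	5	9	4	9	4	4	3
GGT	10	4	7	3	11	4	8	4	4	6	7	5	7	5	6	4	7	6	3	8
GGC	8	4	7	3	3	4	6	8	3	4	4	7	7	3	8	8	5	4	8	4
GGA	5	3	11	4	9	1	9	5	5	3	5	5	5	12	6	5	6	9	2	8
GGG	3	10	7	4	5	6	4	4	9	8	8	7	5	12	4	4	6	9	5	6
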