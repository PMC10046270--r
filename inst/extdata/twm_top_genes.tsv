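gene	cases_mutated	n_cases	tcga_percent
ANK3	4	7	38
BMPER	3	7	12
BRINP2	3	7	13
C6	3	7	24
CTNND2	3	7	14
CSMD1	3	7	40
DNAH5	3	7	56
LAMB4	3	7	15
MUC4	4	7	18
MROH2B	3	7	7
MUC17	3	7	31
PCLO	4	7	49
POM121L12	3	7	13
RELN	3	7	27
TERT	6	7	77
TTN	4	7	80
UNC13C	3	7	30
ZFHX4	4	7	33
ZFPM2	3	7	18
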