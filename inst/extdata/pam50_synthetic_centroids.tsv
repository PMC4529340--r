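gene	LumA	LumB	ERBB2	Basal
ESR1	1	1	-1	-1
PGR	1	1	-1	-1
FOXA1	1	1	-1	-1
MLPH	1	1	-1	-1
NAT1	1	1	-1	-1
SLC39A6	1	1	-1	-1
MAPT	1	1	-1	-1
BAG1	1	1	-1	-1
GPR160	1	1	-1	-1
MDM2	1	1	-1	-1
MKI67	-1	1	0	1
CCNB1	-1	1	0	1
BIRC5	-1	1	0	1
CDC20	-1	1	0	1
UBE2C	-1	1	0	1
RRM2	-1	1	0	1
TYMS	-1	1	0	1
CENPF	-1	1	0	1
KIF2C	-1	1	0	1
CCNE1	-1	1	0	1
ERBB2	0	0	1	0
GRB7	0	0	1	0
FGFR4	0	0	1	0
TMEM45B	0	0	1	0
MMP11	0	0	1	0
KRT5	0	0	0	1
KRT14	0	0	0	1
KRT17	0	0	0	1
FOXC1	0	0	0	1
SFRP1	0	0	0	1
EGFR	0	0	0	1
CDH3	0	0	0	1
PHGDH	0	0	0	1
ACTR3B	0	0	0	1
MYC	0	0	0	1
BCL2	1	0	0	0
BLVRA	1	0	0	0
CDC6	1	0	0	0
ANLN	1	0	0	0
EXO1	1	0	0	0
NDC80	0	1	0	0
PTTG1	0	1	0	0
CEP55	0	1	0	0
UBE2T	0	1	0	0
MELK	0	1	0	0
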