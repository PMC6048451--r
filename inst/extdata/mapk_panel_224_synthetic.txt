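BRAF
ARAF
RAF1
KRAS
NRAS
HRAS
MAP2K1
MAP2K2
MAP2K3
MAP2K4
MAP2K5
MAP2K6
MAP2K7
MAPK1
MAPK3
MAPK4
MAPK6
MAPK7
MAPK8
MAPK9
MAPK10
MAPK11
MAPK12
MAPK13
MAPK14
MAP3K1
MAP3K2
MAP3K3
MAP3K4
MAP3K5
MAP3K6
MAP3K7
MAP3K8
MAP3K11
MAP3K12
MAP3K13
MAP4K1
MAP4K2
MAP4K3
MAP4K4
EGFR
GRB2
SOS1
SOS2
SHC1
PTPN11
RASA1
RASA2
NF1
RASGRF1
RASGRF2
RASGRP1
RASGRP2
RASGRP3
RAP1A
RAP1B
RAP2A
RAP2B
RAP2C
RALA
RALB
RGL1
RGL2
RALGDS
RASSF1
RASSF2
RHEB
RHEBL1
MTOR
AKT1
AKT2
AKT3
PIK3CA
PIK3CB
PIK3CD
PDPK1
PTEN
STAT1
STAT3
JAK1
JAK2
JAK3
ELK1
ELK4
ETS1
ETS2
FOS
JUN
JUNB
JUND
MYC
ATF2
ATF4
CREB1
SRF
MEF2A
MEF2C
DUSP1
DUSP2
DUSP4
DUSP5
DUSP6
DUSP8
DUSP10
DUSP16
PPP3CA
PPP3CB
PPP5C
PPM1A
PPM1B
CALM1
CALM2
CALM3
CAMK2A
CAMK2B
PRKCA
PRKCB
PRKCG
PRKACA
PRKACB
PLA2G4A
PLCB1
PLCG1
CDC42
RAC1
RAC2
RHOA
PAK1
PAK2
STK3
STK4
TAOK1
TAOK2
TAOK3
NGF
NTF3
NTF4
BDNF
NTRK1
NTRK2
FGF2
FGFR1
FGFR2
IGF1
IGF1R
TGFB1
TGFBR1
TGFBR2
TNF
TNFRSF1A
IL1A
IL1B
IL1R1
TP53
MAX
MKNK1
MKNK2
RPS6KA1
RPS6KA2
RPS6KA3
RPS6KA4
RPS6KA5
HSPA8
HSPB1
FLNA
CRK
CRKL
GNA12
GNG12
CACNA1A
PSMA3
PSMA5
PSMB3
PSMB5
PSMD3
APBB1IP
CCDC88A
CNKSR1
SYNGAP1
ZBTB9
UBE2K
FASLG
DAXX
TRAF2
TRAF6
ECSIT
GADD45A
GADD45B
GADD45G
CDKN1A
CASP3
BCL2
BAD
HSPA1A
MAPKAPK2
MAPKAPK3
MAPKAPK5
MAPT
STMN1
LAMTOR3
MAPKX001
MAPKX002
MAPKX003
MAPKX004
MAPKX005
MAPKX006
MAPKX007
MAPKX008
MAPKX009
MAPKX010
MAPKX011
MAPKX012
MAPKX013
MAPKX014
MAPKX015
MAPKX016
MAPKX017
MAPKX018
MAPKX019
MAPKX020
MAPKX021
MAPKX022
MAPKX023
MAPKX024
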