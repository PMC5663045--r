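gene	pathway
EGFR	RTK
ERBB2	RTK
ERBB4	RTK
FLT1	RTK
EPHA2	RTK
EPHB1	RTK
PDGFRA	RTK
MET	RTK
FGFR1	RTK
PIK3CA	PI3K
PIK3CD	PI3K
PIK3R1	PI3K
PIK3R3	PI3K
MTOR	PI3K
PTEN	PI3K
AKT1	PI3K
H3F3A	histone_modifier
HIST1H3B	histone_modifier
ATRX	histone_modifier
ZMYND11	histone_modifier
EP300	histone_modifier
SETD2	histone_modifier
KDM6A	histone_modifier
CREBBP	histone_modifier
TP53	TP53_pathway
PPM1D	TP53_pathway
MDM2	TP53_pathway
CHEK2	TP53_pathway
ITGA2	integrin
ITGA7	integrin
ITGB3	integrin
ITGB4	integrin
CDH1	cadherin
CDH5	cadherin
CDH11	cadherin
PCDH15	cadherin
FAT1	cadherin
IDH1	other
ACVR1	other
NF1	other
BRAF	other
BCOR	other
CDKN2A	other
MLH1	other
RAD50	other
LZTR1	other
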