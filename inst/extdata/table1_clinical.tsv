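molecular_group	case_id	age_years	sex	primary_dx	recurrence_dx	ttp_months	interval_months	location	sublocation	surgery1	surgery2	germline_available	treatments
H3/IDH1 mutant	HGG1	14	M	GBM	GBM	8.7	16.2	midline	Spine	GTR	NA (autopsy)	Yes	RT+ TMZ, TMZ
H3/IDH1 mutant	HGG2	18	F	AA	GBM	10.3	14.4	midline	Pons	STR	NA (autopsy)	Yes	RT+ TMZ, TMZ, bevacizumab, vorinostat
H3/IDH1 mutant	HGG3	13	F	GBM	GBM	6.5	6.5	midline	Spine	STR	NA (autopsy)	Yes	RT+ TMZ, rapamycin
H3/IDH1 mutant	HGG4	4	F	GBM	GBM	23.5	23.5	midline	Pons	Biopsy	NA (autopsy)	No	RT + vandatenib, dasatinib
H3/IDH1 mutant	HGG5	12	M	GBM	GBM	7.1	8.7	hemisphere	NA	GTR	NA (autopsy)	No	RT + TMZ, TMZ + bevacizumab
H3/IDH1 mutant	HGG6	29	F	AA focal GBM	GBM	45.2	45.2	hemisphere	NA	STR	STR	No	RT + TMZ, TMZ
H3/IDH1 mutant	HGG7	19	F	AA	AA	14.3	14.3	hemisphere	NA	GTR	GTR	No	Surgery
H3/IDH1 wildtype	HGG8	15	F	AA	GBM	12	13	midline	Thalamus	Biopsy	NA (autopsy)	Yes	RT+ bevacizumab + TMZ, bevacizumab + TMZ + irinotecan
H3/IDH1 wildtype	HGG9	18	M	GBM	GBM	25.3	25.3	hemisphere	NA	GTR	STR	Yes	RT, bevacizumab + irinotecan
H3/IDH1 wildtype	HGG10	10	F	HGG Gr III w neuronal component	HGG Gr IV w neuronal component	9.3	17.3	hemisphere	NA	GTR	STR	Yes	RT, lapatinib + bevacizumab, VP16
H3/IDH1 wildtype	HGG11	14	F	GBM	GBM	3.8	7.1	hemisphere	NA	Biopsy	NA (autopsy)	Yes	RT + TMZ, bevacizumab
H3/IDH1 wildtype	HGG12	17	M	GBM	GBM	29.1	29.1	hemisphere	NA	STR	STR	No	RT, VP16, BMT
H3/IDH1 wildtype	HGG13	19	M	AA	AA	39.2	39.2	hemisphere	NA	GTR	GTR	No	RT+ TMZ, TMZ
H3/IDH1 wildtype	HGG14	12	M	GBM	GBM	13.8	13.8	hemisphere	NA	GTR	GTR	No	RT + TMZ, TMZ + lomustine
NF1 germline	HGG15	15	M	AA	GBM	42.4	65.4	hemisphere	NA	GTR	NA (autopsy)	Yes	RT, cisplatin + cyclophosphamide + topotecan + vincristine, TMZ, bevacizumab, rapamycin, cabozantinib
NF1 germline	HGG16	23	F	LGG Gr II w pilocytic features	GBM	9.5	9.5	hemisphere	NA	GTR	STR	Yes	Surgery
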