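allele	drug	reaction	population	citation
C*01:02	Methazolamide	SJS/TEN	Korean, Japanese	PMID_methazolamide
C*03:02	Allopurinol	DRESS, SJS/TEN	Korean, Vietnamese	PMID_allopurinol_c0302
B*58:01	Allopurinol; Carbamazepine; Lamotrigine	SCAR, DRESS, SJS/TEN	Asian, European	PMID_allopurinol_b5801
B*13:01	Dapsone; Phenytoin	HSS, DRESS, SJS/TEN	Asian	PMID_dapsone
DPB1*03:01	Aspirin	Asthma	Korean	PMID_aspirin
B*15:02	Carbamazepine; Phenytoin; Lamotrigine	SJS/TEN	Asian	PMID_carbamazepine_b1502
B*35:01	Nevirapine	HSS, DRESS	Multiple ethnicities	PMID_nevirapine_b3501
A*31:01	Carbamazepine; Lamotrigine	SCAR, DRESS, SJS/TEN	Multiple ethnicities	PMID_carbamazepine_a3101
B*15:11	Carbamazepine	DRESS, SJS/TEN	Asian	PMID_carbamazepine_b1511
DRB1*01:01	Nevirapine	DRESS, HSS	Asian, Australian	PMID_nevirapine_drb10101
B*57:01	Abacavir; Flucloxacillin	DRESS, HSS, DILI	Multiple ethnicities	PMID_abacavir
B*59:01	Methazolamide; Carbamazepine	SJS/TEN	Asian, Japanese	PMID_methazolamide_b5901
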