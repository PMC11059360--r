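gene	protein_change	clinical_significance	pocket_distance	depth	boundary_distance	relative_burial	lipid_facing	helix_context	hbond_loss	half_thickness	reported_category
SLC26A2	D111Y	Pathogenic	22	13	2	0.60	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	Q125L	Pathogenic	5	2	13	0.05	FALSE	TRUE	FALSE	15	substrate_site
SLC26A2	A133V	Pathogenic	16	5	10	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	S157P	Pathogenic	24	-13	2	0.60	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	G166R	Pathogenic	4	-1	14	0.10	FALSE	TRUE	FALSE	15	substrate_site
SLC26A2	D250V	Pathogenic	14	-18	3	0.60	FALSE	TRUE	FALSE	15	unexplained
SLC26A2	R279W	Pathogenic	30	16	1	0.65	TRUE	FALSE	FALSE	15	lipid_interface
SLC26A2	C311R	Pathogenic	18	-4	11	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	A386V	Pathogenic	15	3	12	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	A386G	Likely pathogenic	15	3	12	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	N425D	Pathogenic	13	0	15	0.10	FALSE	TRUE	TRUE	15	fold_destabilizing
SLC26A2	I426T	Pathogenic	20	0	15	0.70	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	I426N	Likely pathogenic	20	0	15	0.70	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	Q454P	Pathogenic	25	14	1	0.60	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	A461V	Pathogenic	17	-6	9	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	L483P	Pathogenic	19	7	8	0.08	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	G484D	Pathogenic	19	8	7	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	W505R	Pathogenic	26	-14	1	0.60	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	T512K	Pathogenic	24	-13	2	0.60	TRUE	TRUE	FALSE	15	lipid_interface
SLC26A2	S522F	Pathogenic	18	-2	13	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	C653S	Pathogenic	40	-30	15	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	C653Y	Pathogenic	40	-30	15	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	C653G	Likely pathogenic	40	-30	15	0.05	FALSE	TRUE	FALSE	15	fold_destabilizing
SLC26A2	G678V	Pathogenic	42	-32	17	0.05	FALSE	FALSE	FALSE	15	fold_destabilizing
SLC26A2	A715T	Pathogenic	43	-33	18	0.05	FALSE	FALSE	FALSE	15	fold_destabilizing
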