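family_id	correlated_domain	count
CBM50	LysM Domain	1
GH1	Glyco_hydro_1	14
GH4	Glyco_hydro_4	2
GH7	Glyco_hydro_7	1
GH8	Glyco_hydro_8	3
GH9	Glyco_hydro_9	3
GH16	Glyco_hydro_16	5
GH17	Glyco_hydro_17	3
GH18	Glyco_hydro_18	2
GH19	Glyco_hydro_19	1
GH20	Glyco_hydro_20	1
GH22	Lys, C-type lysozyme	1
GH24	lysozyme	1
GH26	Glyco_hydro_26	2
GH30	Glyco_hydro_30	1
GH31	Glyco_hydro_31	7
GH35	Glyco_hydro_35	1
GH37	Trehalase	3
GH47	Glyco_hydro_47	1
GH57	Glyco_hydro_57	2
GH65	Glyco_hydro_65	2
GH89	a-N-acetyl glucosaminidase	2
GH102	transglycosylase	1
CE4	Polysaccharide deacetylase	4
CE8	Pectinesterase	1
CE11	UDP-3-O-acyl N-acetylglycosamine deacetylase	1
CE14	GlcNAc-PI de-N-acetylase	2
PL1	Pec_lyase_C	1
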