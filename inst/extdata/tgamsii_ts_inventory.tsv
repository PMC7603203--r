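jgi_id	gene	putative_function	group	subtype	include_override
Trigam1|5596	TC4	bifunctional HAD-like	had_bifunctional
Trigam1|4742	TRI5	trichodiene synthase	tri5
Trigam1|162	TS5	pentalenene synthase	pentalenene
Trigam1|9843	TS7	sesquiterpene synthase	tsc_unchar3
Trigam1|1824	TS4	sesquiterpene synthase	tri5_unchar1
Trigam1|4947	TS3	sesquiterpene synthase	tri5_unchar2
Trigam1|5367	TS1	uncharacterized group 4	tsc_unchar4
Trigam1|340	TS6	squalene synthase	squalene_synthase
Trigam1|3208	TC3	geranylgeranyl transferase I	protein_prenylation	GGTase1
Trigam1|5139	TC5	geranylgeranyl transferase II	protein_prenylation	GGTase2
Trigam1|3927	TC1	farnesyl transferase	protein_prenylation	FTase
Trigam1|4065	TS8	GGPP synthase	polyprenyl_superfamily	GGPP_synthase
Trigam1|2917	TS10	FPP synthase	polyprenyl_superfamily	FPP_synthase
Trigam1|9898	TS9	indole diterpene synthase	polyprenyl_superfamily	indole_diTS
Trigam1|8345	TC2	oxidosqualene cyclase	oxidosqualene_cyclase
Trigam1|6072	TS11	uncharacterized group 5	sqs_psy_unchar5
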