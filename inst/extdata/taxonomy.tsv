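id	display_name	required_domains	required_motifs	forbidden_domains	needs_tm	precedence
had_bifunctional	bifunctional HAD-like TS	PF13419|IPR008930	ddxxe|dxdtt		FALSE	1
tri5	trichodiene synthase (TRI5)	PF06330|PIRSF001388	tri5_aspartate|tri5_triad		FALSE	2
longiborneol	longiborneol synthase	PF06330	ddhfd		FALSE	3
tri5_unchar1	TRI5 superfamily uncharacterized group 1	PF06330	ddxxe		FALSE	4
tri5_unchar2	TRI5 superfamily uncharacterized group 2	PF06330	ddxxd		FALSE	5
presilphiperfolanol	presilphiperfolan-8-beta-ol synthase	PF03936	ddxxe		FALSE	6
pentalenene	pentalenene synthase	PF03936	nsd|dte		FALSE	7
tsc_unchar3	terpene synthase C uncharacterized group 3	PF03936	ddxxd		FALSE	8
tsc_unchar4	terpene synthase C uncharacterized group 4	PF03936	class1_aspartate		FALSE	9
squalene_synthase	squalene synthase (SQS)	PF00494|PTHR11626:SF2|PS01044			TRUE	10
protein_prenylation	protein prenylation enzymes	PTHR11774:SF4,PTHR11774:SF11,PTHR11774:SF6			FALSE	11
oxidosqualene_cyclase	oxidosqualene cyclase (OSC)	PF13249|PF13243|PTHR11764|PS01074	dctae|qw		FALSE	12
sqs_psy_unchar5	SQS-PSY domain uncharacterized group 5	PF00494|PTHR21181:SF13			FALSE	13
class2_diterpene	Class II diterpene synthase (CPS/KS-like)	PTHR31739:SF4	dxdd		FALSE	14
polyprenyl_superfamily	polyprenyl synthase superfamily	PF00348	ddxxd		FALSE	15
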