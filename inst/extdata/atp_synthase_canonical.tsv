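complex	gene_id	stoichiometry	operon_id	note
atp_synthase_cf1cf0	atpA	3	atp1	alpha subunit; canonical literature stoichiometry, external knowledge (not derived from this package's data)
atp_synthase_cf1cf0	atpB	3	atp2	beta subunit
atp_synthase_cf1cf0	atpC	1	nuclear	gamma subunit (nuclear-encoded)
atp_synthase_cf1cf0	atpD	1	nuclear	delta subunit (nuclear-encoded)
atp_synthase_cf1cf0	atpE	1	atp1	epsilon subunit
atp_synthase_cf1cf0	atpF	1	atp2	b subunit (CF0 I)
atp_synthase_cf1cf0	atpG	1	nuclear	b' subunit (CF0 II, nuclear-encoded)
atp_synthase_cf1cf0	atpH	14	atp1	c subunit ring (CF0 III)
atp_synthase_cf1cf0	atpI	1	atp1	a subunit (CF0 IV)
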