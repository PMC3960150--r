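fusion_type	gene1	gene2	sample	RESPER	evidence
read-through	FGFR3	TACC3	1835	108.2	known
intra	EGFR	CO9	5209	89.3	amplicon
read-through	KIF5A	BC033961	0618	74.5	misannotation
intra	DTX3	FRS2	2571	74.0	off_frame
read-through	VSTM2A	EGFR	0747	72.9	amplicon
read-through	EGFR	LANCL2	0211	67.5	amplicon
intra	AK293540	AGAP3	2528	63.7	off_frame
cis	LANCL2	PSPH	0817	52.8	amplicon
intra	BCAN	NTRK1	2619	50.7	clean
cis	LANCL2	SEPT14	0211	48.6	amplicon
cis	SEC61G	EGFR	2554	45.5	amplicon
intra	SDK1	EGFR	2557	38.3	amplicon
intra	MARCH9	SUDS3	5856	36.6	no_junction
read-through	KIF5A	BC033961	1980	34.9	misannotation
read-through	FGFR3	TACC3	4925	32.4	known
cis	OS9	C12orf66	0174	31.8	off_frame
intra	NFASC	NTRK1	5411	31.7	clean
read-through	KIF5A	BC033961	5651	30.4	misannotation
intra	YEATS4	XRCC6BP1	0138	30.4	clean
read-through	KIF5A	BC033961	2558	29.3	misannotation
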