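# Worked classification cases: itraconazole / PVP K30 dispersions.
# tg_events encodes value:width pairs (deg C), semicolon-separated.
drug	polymer	drug_loading	method	replicate	tg_events	melting_detected	recrystallization_detected	mesophase_endotherms	xrpd_crystalline
ITR	PK30	0.4	SD	1	95:12	FALSE	FALSE	0	FALSE
ITR	PK30	0.6	QC	1	58.9:10	FALSE	FALSE	2	FALSE
ITR	PK30	0.6	SD	1	58.9:10	FALSE	TRUE	2	FALSE
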