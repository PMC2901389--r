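gene	matrix_id	offset	strand	mss	css	conserved
PGENE0001	SYNTH	1575	+	0.9	1	FALSE
PGENE0012	SYNTH	1849	+	0.9	0.8	FALSE
PGENE0038	SYNTH	688	+	0.9	1	FALSE
PGENE0039	SYNTH	1032	-	0.9	1	FALSE
PGENE0040	SYNTH	1825	-	0.9	0.8	FALSE
PGENE0053	SYNTH	336	+	0.9	0.8	FALSE
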