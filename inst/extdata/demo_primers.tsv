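# Demo primer list (SYNTHETIC): sequences drawn from the packaged
# synthetic reference; orientation R primers are given 5'->3' on the
# reverse strand, as in standard primer catalogs.
name	sequence	orientation
synA008F	AAGCGGACGGTACCGGTGCG	F
synKb366F	CCGAGCTAAATCTCGCGAGC	F
syn515Fdeg	CTGCAGTCGRCGTGYGGGCT	F
synAb779F	CAAGCCAGAGCACCACCACG	F
synAb909R	CGCATGGTCCTCCGACACTC	R
synU1406R	CCCGAGCCGACGCCGCGTTC	R
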