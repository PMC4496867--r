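# Hypervariable regions V1-V9 of the 16S rRNA gene, standard E. coli
# numbering, 1-based inclusive intervals. Interval set follows the
# commonly used amplicon-design convention on the rrnB frame.
name	start	end	source
V1	69	99	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V2	137	242	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V3	433	497	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V4	576	682	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V5	822	879	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V6	986	1043	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V7	1117	1173	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V8	1243	1294	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
V9	1435	1465	E. coli 16S hypervariable-region interval convention (Brosius rrnB frame)
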