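# Curated inventory of intron insertion loci in archaeal 16S rRNA genes.
# locus: standard E. coli-numbered position directly before the insertion.
# n_cds: homing-endonuclease CDS introns (cds_m1/cds_m2 = with one/two
# LAGLI-DADG motif copies); n_hp: short (<50 nt) hairpin introns;
# n_pru: partial/remnant/uncharacterized. primers: 'universal' archaeal
# primers whose annealing site spans the locus (semicolon-separated).
locus	taxa	n_cds	cds_m1	cds_m2	n_hp	n_pru	primers	note
374	Pyrobaculum;Caldivirga	5	5	0	1	0	Kb366F	
548	Pyrobaculum;Thermoproteus;Staphylothermus;Desulfurococcales	2	0	2	13	0		
722	Caldiarchaeum	0	0	0	0	2		
781	Pyrobaculum;Thermoproteus;Vulcanisaeta;Thermoproteales;Caldivirga;Caldiarchaeum	14	2	4	0	28	Ab779F	cds+pru totals 42 vs printed per-locus max 41; transcribed as-is
803	Desulfurococcales	0	0	0	0	3	Ab789F;Arc806R	
901	Pyrobaculum;Caldivirga;Desulfurococcales	0	0	0	8	0	Ab909R	
908	Pyrobaculum;Caldivirga;Aeropyrum;Caldiarchaeum	4	1	3	0	6	Ab909R;Ab906F;926wF;U926R;Ab927R	
919	Pyrobaculum;Thermoproteus;Caldivirga;Vulcanisaeta;Caldiarchaeum;Desulfurococcales	6	2	3	2	7	Ab906F;926wF;U926R;Ab927R;A934R	hp/pru split ambiguous in published layout
978	Caldiarchaeum	0	0	0	9	0		
1093	Pyrobaculum;Thermoproteus;Desulfurococcales	15	4	11	7	9		hp/pru split ambiguous in published layout
1205	Pyrobaculum;Thermoproteus;Desulfurococcales	2	0	2	17	0		cds entry conflicts with text stating locus is hairpin-only
1213	Pyrobaculum;Thermoproteus	18	4	14	0	2		
1391	Pyrobaculum;Thermoproteus;Vulcanisaeta	15	7	2	0	5	UA1406R;N1406R;U1406R	
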