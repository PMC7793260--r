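# Muropeptide composition (percent peak area) of E. coli LMC500 strains
# carrying no plasmid or the indicated expression plasmids; published HPLC
# values, mean of two biological replicates. Species names follow Glauner
# nomenclature. Dimer anhydro/LysArg rows are overlapping annotations of the
# peptide-length rows (in_total = FALSE); monomer sub-rows are disjoint.
species	oligomer_class	row_type	peptide_lengths	modification	in_total	LMC500	LMC500_mKO	LMC500_mKO_PBP2WT	LMC500_mKO_PBP2L61R	LMC500_mKO_GlpT
Monomers (total)	monomer	total	NA	-	FALSE	52.6	52.0	52.1	52.2	52.2
dipeptides	monomer	species	2	-	TRUE	1.4	1.6	1.3	1.2	1.4
tripeptides	monomer	species	3	-	TRUE	5.0	5.0	5.0	4.0	4.7
tetrapeptides	monomer	species	4	-	TRUE	41.6	41.0	41.3	43.3	41.8
anhydro	monomer	species	NA	anhydro	TRUE	0.9	1.0	1.0	0.7	1.0
LysArg	monomer	species	NA	LysArg	TRUE	3.7	3.4	3.5	3.0	3.4
Dimers (total)	dimer	total	NA	-	FALSE	40.5	40.8	40.2	41.7	40.7
tetratripeptide	dimer	species	4+3	-	TRUE	3.1	3.0	3.0	2.2	2.9
tetratetrapeptide	dimer	species	4+4	-	TRUE	36.0	36.3	35.0	37.1	36.0
anhydro	dimer	species	NA	anhydro	FALSE	2.0	2.1	2.2	1.7	2.0
LysArg	dimer	species	NA	LysArg	FALSE	1.6	1.7	1.5	1.2	1.6
Trimers (total)	trimer	total	NA	-	FALSE	4.4	4.6	4.8	3.8	4.5
Chain ends (anhydro)	chain_ends	chain_ends	NA	anhydro	FALSE	2.3	2.4	2.5	1.9	2.3
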