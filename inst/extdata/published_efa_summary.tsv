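# Published acceptor FRET efficiencies (spectrofluorimeter, mKO donor /
# mCherry acceptor fusions in E. coli LMC500): group mean, sample SD and
# number of biological repeats. mecillinam block: + 2 mg/L mecillinam.
group	condition	mean_efa	sd	n
tandem	none	31.0	4.0	22
RodA_GlpT_negative	none	1.1	3.5	24
RodA_PBP2WT	none	12.7	1.7	16
RodA_R109A_PBP2	none	12.5	1.9	4
RodA_Q207R_PBP2	none	12.7	1.2	4
RodA_PBP2_S330C	none	10.2	1.4	4
RodA_MalFNT_PBP2	none	11.8	4.1	6
RodA_MalF37_PBP2	none	8.2	1.3	3
RodA_PBP2_L61R	none	10.8	3.0	8
RodA_RodA	none	5.5	1.4	4
MreBSW_RodA	none	7.2	3.4	4
PBP2_PBP2	none	9.2	0.5	4
PBP2_MalFNT_PBP2	none	10.5	2.0	4
MreC_PBP2WT	none	5.1	1.2	6
MreC_MalFNT_PBP2	none	5.4	1.7	6
MreC_PBP2_L61R	none	5.3	0.6	2
MreD_PBP2WT	none	4.3	1.2	10
MreD_MalFNT_PBP2	none	5.3	1.6	10
MreCD_PBP2WT	none	3.3	0.5	6
MreCD_MalFNT_PBP2	none	5.4	1.1	5
tandem	mecillinam	30.3	2.7	4
RodA_GlpT_negative	mecillinam	1.0	1.6	4
RodA_PBP2WT	mecillinam	7.9	1.8	8
RodA_MalFNT_PBP2	mecillinam	6.2	1.1	4
RodA_MalF37_PBP2	mecillinam	3.0	2.0	4
RodA_PBP2_S330C	mecillinam	6.6	1.7	4
RodA_PBP2_L61R	mecillinam	6.3	3.5	7
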