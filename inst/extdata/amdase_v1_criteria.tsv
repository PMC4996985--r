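index	kind	positions	residues	strict_positions	note
1	residue_pair	14,15	P,P		Part of large binding pocket
2	residue_pair	75,76	T,S		Part of dioxyanion hole
3	single_residue	126	Y		Part of dioxyanion hole
4	single_residue	189	G		Part of dioxyanion hole
5	single_residue	40	L		Building block of hydrophobic binding pocket
6	single_residue	43	V		Building block of hydrophobic binding pocket
7	single_residue	48	Y		Building block of hydrophobic binding pocket
8	single_residue	156	V		Building block of hydrophobic binding pocket
9	single_residue	159	M		Building block of hydrophobic binding pocket
10	residue_pair	74,188	G,C	74,188	Gly74 distinguishes AMDases from the racemases' second active-site Cys; Cys188 is the proton donor
11	octamer_motif	72-79	LMGTSLSF	74	Conserved motif surrounding stereochemistry-determining residues
12	octamer_motif	184-191	ILLSCGGL	188	Conserved motif surrounding stereochemistry-determining residues
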