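index	pattern	start	end	starred	note
1	GLIVPPAxGxVPxE	10	23	14,15	Binding of aromatic residues
2	GLGLxxVxxxGY	37	48	40,43,48	Destabilization of leaving carboxylate group
3	GAxxVxLMGTSLSFYRG	66	82	74,75,76	G74 determines product stereochemistry; dioxyanion-hole hydrogen bonds
4	RVAVxTAY	119	126	126	Dioxyanion-hole hydrogen bond
5	LxIxxVxxM	151	159	156,159	Destabilization of leaving carboxylate group
6	DALLISCGxL	182	191	188,189	Active-site Cys determines product stereochemistry
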