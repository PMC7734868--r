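name	smarts
aromatic_nitro	c[$([NX3](=O)=O),$([NX3+](=O)[O-])]
aromatic_amine	c[NX3;H2,H1;!$(NC=O)]
n_nitroso	[NX3][NX2]=O
epoxide	C1OC1
aziridine	C1NC1
acyl_halide	[CX3](=O)[F,Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
primary_alkyl_halide	[CH2][Cl,Br,I]
azide	N=[N+]=[N-]
boronic_acid	B(O)O
michael_acceptor	[CX3]=[CX3][CX3]=O
hydrazine	[NX3][NX3]
alkyl_sulfonate_ester	[#6]OS(=O)(=O)[#6]
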