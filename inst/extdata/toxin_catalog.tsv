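name	pdb_id	d_max_nm	molar_mass_g_mol	molar_mass_source	c_normal_value	c_normal_unit
Endothelin	1EDN	2.6	2492	endothelin-1 peptide, monoisotopic-average formula mass (UniProt P05305 mature ET-1)	28.8	ng/L
Cystatin C	3GAX	4.08	13343	mature human cystatin C, average mass (UniProt P01034, residues 27-146)	1.6	mg/L
Retinol-binding protein	1BRP	4.9	NA	NA	NA	NA
Complement Factor D	1DSU	5.12	NA	NA	NA	NA
Interleukin-6	1ALU	5.18	20900	mature human interleukin-6, average mass (UniProt P05231)	13.3	ng/L
Tumor necrosis factor-alpha	3GIO	5.79	NA	NA	NA	NA
Interleukin-1 beta	3LTQ	6.04	NA	NA	NA	NA
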