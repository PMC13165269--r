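label,theta_mdeg_208,protein_conc_M,n_residues,path_cm
native,-61.1247,5e-6,585,0.1
glycated,-38.0373,5e-6,585,0.1
treated_200uM,-53.2825,5e-6,585,0.1
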