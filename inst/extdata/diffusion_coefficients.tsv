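# Aqueous diffusion coefficients used to rescale the measured K+ exchange
# time constant to the ligand of interest (tau scales as 1/D at fixed
# geometry). cGMP is assigned the published cAMP value (structurally
# closest molecule with a measured coefficient).
species	D_cm2_per_s
K	1.96e-5
cAMP	4.4e-6
cGMP	4.4e-6
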