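source_label,value,convention,fe_per_particle,particle_molar_mass,note
molar_fe_a,5.9e-3,cgs_per_mol_fe,2400,NA,CGS emu per mol Fe; Curie-law fit gives mu_eff = 3.78 mu_B per Fe
molar_fe_b,6.05e-3,cgs_per_mol_fe,2400,NA,CGS emu per mol Fe
mass_si,2.5e-4,si_per_mass,2400,5.8e5,SI A*m^2/(g*T) per unit sample mass; loaded ferritin ~580 kDa
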