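id,kind,description,n_atoms,unpaired_electrons,temperature_K,claimed_alignment,xi_J_per_T2,radius_m,B_T,gradient_T_per_m,gradient_T_per_m_printed,slp_W_per_g,slp_is_upper_bound,ref_field_kA_per_m,ref_frequency_kHz,ac_field_kA_per_m,ac_frequency_kHz,fe_per_particle,conductivity_W_per_mK,boundary_conductance_W_per_m2K,cell_radius_m,n_particles,tissue_density_g_per_m3,provenance
qin-compass,compass,Rod-shaped 40-Fe protein complex claimed to align with the geomagnetic field,40,5,298,0.45,NA,NA,5e-5,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,40 iron atoms with at most 5 unpaired electrons each; Earth field ~50 uT; room temperature; claimed alignment fraction 0.45
wheeler-static,static,Ferritin tethered to a TRPV4 channel and pulled by a static field,NA,NA,298,NA,2.4e-22,6e-9,0.05,6.6,7,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,reported static field ~0.05 T with gradient ~6.6 T/m (7 T/m in the displayed arithmetic); ferritin shell radius 6 nm; consensus magnetizability 2.4e-22 J/T^2
highfield-5T,static,Practical-limit extrapolation of the static-force scenarios to a 5 T field,NA,NA,298,NA,2.4e-22,6e-9,5,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,100-fold larger field (5 T); no gradient assumed; dipole-pair and anisotropy mechanisms only
stanley-heating,heating,Ferritin tethered to a TRPV1 channel and driven by an AC field,NA,NA,298,NA,2.4e-22,6e-9,NA,NA,NA,30,FALSE,25.5,465,25.5,465,2400,0.61,2e8,5e-6,1e4,1.03e6,engineered upper-bound SLP of 30 W per g of metal at 25.5 kA/m and 465 kHz; 2400 Fe per ferritin; 1e4 complexes on a 5-um-radius cell; brain density 1.03 g/cm^3
ferritin-measured,heating,Magnetite-core ferritin at its measured (non-detectable) heating bound,NA,NA,298,NA,2.4e-22,6e-9,NA,NA,NA,0.01,TRUE,12.4,183,25.5,465,2400,0.61,2e8,5e-6,1e4,1.03e6,reconstituted magnetite-core ferritin showed no measurable heating: SLP below 0.01 W/g at 12.4 kA/m and 183 kHz
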