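reference,material,d_nm,H_kA_per_m,f_kHz,slp_W_per_g,slp_is_upper_bound,slp_corr_printed_W_per_g,printed_sig_digits,notes
fortin2007,Fe2O3,5.3,24.8,700,4,FALSE,2.8,2,
fortin2007,Fe2O3,6.7,24.8,700,14,FALSE,10,1,
fortin2007,Fe2O3,8,24.8,700,37,FALSE,26,2,
magnetite_8nm,Fe3O4,8,12,183,36.5,FALSE,75,2,
hergt2004,Fe2O3,7,15,410,15,FALSE,49,2,
ferritin_magnetite,ferritin with Fe3O4 core,6,12.4,183,0.01,TRUE,0.1,1,per mass of only the metal ions
ferritin_cobalt,ferritin with Co0.15Fe2.85O4 core,6.8,12.4,183,2.8,FALSE,130,2,per mass of only the metal ions
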