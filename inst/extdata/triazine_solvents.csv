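solvent,polarity_class,eps,n,etn,viscosity_cp,lambda_abs_nm,lambda_em_nm,epsilon_m1cm1,phi_f,stokes_shift_printed_cm1,delta_f_printed,f_printed,mu12_printed_debye
cyclohexane,nonpolar,2.02,1.4235,0.006,NA,358.5,467.5,7911,0.015,6503.6,0.008,0.23,4.05
dioxane,polar_aprotic,2.25,1.4224,0.164,NA,357.5,456.5,7867,0.008,6066.2,0.024,0.22,3.92
thf,polar_aprotic,7.58,1.4072,0.207,NA,361,455.5,7422,0.012,5746.9,0.210,0.228,3.99
dmf,polar_aprotic,36.71,1.4305,0.404,0.92,348.5,465.5,6933,0.022,7212.1,0.275,0.23,3.97
dmso,polar_aprotic,46.68,1.479,0.444,1.99,346,465.5,6489,0.019,7419.5,0.263,0.213,3.83
propanol,polar_protic,20.1,1.3856,0.617,NA,359,470.5,8497,0.023,6601.2,0.274,0.249,4.17
ethanol,polar_protic,24.55,1.3614,0.654,NA,357,480.5,7289,0.022,7199.5,0.288,0.219,3.9
methanol,polar_protic,32.6,1.326,0.762,NA,354.5,490,7333,0.017,7800.6,0.308,0.237,4.06
ethylene_glycol,polar_protic,37,1.43,0.792,NA,354,496,7067,0.025,8087.3,0.274,0.244,4.12
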