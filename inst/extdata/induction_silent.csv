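S,t_ind_s,T_K,ultrasound_W,printed_ln_t,printed_gamma_mJ_m2,printed_N_c,printed_dG_c_J_mol,printed_r_c_nm,note
1.8,25200,298.15,0,10.134,4.578,3.160,1538.40,0.36,ln(25200)=10.1346 rounds to 10.135; source prints 10.134
1.9,23400,298.15,0,10.060,4.578,2.427,1290.14,0.33,
1.95,21960,298.15,0,9.996,4.578,,1191.73,0.32,source N_c entry unparseable ("2.1.55"); stored as missing
2,21600,298.15,0,9.980,4.578,1.927,1106.27,0.31,
2.1,18000,298.15,0,9.798,6.963,5.530,3398.02,0.44,
2.2,16200,298.15,0,9.692,6.963,4.608,3008.87,0.41,
2.3,12600,298.15,0,9.441,6.963,3.909,2696.28,0.39,
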