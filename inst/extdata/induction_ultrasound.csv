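S,t_ind_s,T_K,ultrasound_W,printed_ln_t,printed_gamma_mJ_m2,printed_N_c,printed_dG_c_J_mol,printed_r_c_nm,note
1.8,19800,298.15,100,9.893,5.552,5.636,2743.888,0.44,
1.9,15840,298.15,100,9.670,5.552,4.328,2301.089,0.41,
1.95,15840,298.15,100,9.670,5.552,3.843,2125.567,0.39,
2,14400,298.15,100,9.574,5.552,3.437,1973.126,0.37,
2.1,12600,298.15,100,9.441,7.234,6.199,3809.599,0.46,
2.2,10800,298.15,100,9.287,7.234,5.166,3373.318,0.43,
2.3,9000,298.15,100,9.105,7.234,4.382,3022.863,0.41,
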