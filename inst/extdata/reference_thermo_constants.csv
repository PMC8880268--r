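compound,temperature_K,Ka_per_M,n_sites,dG_kJ_mol,dS_J_mol_K,dH_kJ_mol
magnolol,298,2.97e5,0.39,-2.92,121.83,39.23
magnolol,304,4.54e5,0.42,-2.19,121.83,39.23
magnolol,310,5.48e5,0.65,-1.46,121.83,39.23
luteolin,298,24.86e5,1.10,-2.29,-22.95,-9.13
luteolin,304,23.99e5,1.28,-2.15,-22.95,-9.13
luteolin,310,21.54e5,1.34,-2.01,-22.95,-9.13
acarbose,298,3.91e5,1.77,2.60,-161.47,-45.51
acarbose,304,1.94e5,1.38,3.57,-161.47,-45.51
acarbose,310,1.93e5,1.36,4.54,-161.47,-45.51
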