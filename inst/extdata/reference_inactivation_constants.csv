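compound,concentration_uM,k_per_s,ddG_kJ_mol
magnolol,10,2.78e-4,21.10
magnolol,25,2.81e-4,21.08
magnolol,50,2.81e-4,21.07
magnolol,100,2.85e-4,21.04
luteolin,5,2.67e-4,21.21
luteolin,10,2.78e-4,21.10
luteolin,25,2.81e-4,21.07
luteolin,40,2.82e-4,21.06
luteolin,50,2.84e-4,21.05
acarbose,200,2.76e-4,21.12
acarbose,400,2.81e-4,21.07
acarbose,800,2.83e-4,21.06
acarbose,1600,2.84e-4,21.05
acarbose,3200,2.85e-4,21.04
acarbose,4000,2.85e-4,21.03
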