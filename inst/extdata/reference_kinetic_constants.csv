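compound,inhibitor_uM,Km_mM,kcat_per_s,kcat_over_Km,Ki_uM,Ki_prime_uM,potency
magnolol,0,0.48,3.89,8.18,78.3,132.4,4.5
magnolol,10,0.53,3.59,6.78,,,
magnolol,25,0.59,3.29,5.54,,,
magnolol,50,0.54,2.86,5.52,,,
magnolol,100,0.58,2.22,3.87,,,
luteolin,0,0.32,3.52,11.01,34.2,35.4,10.4
luteolin,5,0.35,2.95,8.43,,,
luteolin,10,0.37,2.65,7.17,,,
luteolin,25,0.36,2.02,5.60,,,
luteolin,40,0.36,1.78,4.94,,,
luteolin,50,0.37,1.41,3.81,,,
acarbose,0,0.30,2.92,9.75,356.3,,1
acarbose,200,0.91,2.83,3.11,,,
acarbose,400,1.31,2.87,2.19,,,
acarbose,800,1.96,2.77,1.41,,,
acarbose,1600,3.24,2.66,0.82,,,
acarbose,3200,5.91,2.79,0.47,,,
acarbose,4000,8.30,3.12,0.38,,,
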