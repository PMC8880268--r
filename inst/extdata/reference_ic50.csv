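compound,enzyme_uM,ic50_M,neg_log_ic50
magnolol,0.025,2.83e-5,4.55
magnolol,0.05,2.85e-5,4.55
magnolol,0.075,3.26e-5,4.49
luteolin,0.025,1.40e-5,4.85
luteolin,0.05,2.16e-5,4.66
luteolin,0.075,3.23e-5,4.49
luteolin,0.125,5.94e-5,4.23
acarbose,0.025,80.54e-5,3.09
acarbose,0.05,86.80e-5,3.06
acarbose,0.075,81.54e-5,3.09
acarbose,0.125,80.70e-5,3.09
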