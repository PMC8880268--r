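compound,temperature_K,Ksv_per_M,Kq_per_M_s
magnolol,298,3.89e5,3.90e13
magnolol,304,4.22e5,4.22e13
magnolol,310,5.30e5,5.30e13
luteolin,298,23.22e5,23.22e13
luteolin,304,21.73e5,21.73e13
luteolin,310,18.68e5,18.68e13
acarbose,298,3.75e5,3.75e13
acarbose,304,1.89e5,1.89e13
acarbose,310,1.80e5,1.80e13
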