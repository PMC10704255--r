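label,thickness_um,mean_velocity_m_s,velocity_sd,mean_modulus_kpa,modulus_sd,n_repeats
10,496,7.97,0.18,191.66,13.43,3
15,530,8.02,0.33,194.60,16.28,3
20,482,8.35,0.33,210.61,22.71,3
25,560,8.70,0.27,273.59,30.46,3
30,521,9.91,0.30,369.98,34.24,3
35,530,10.56,0.15,439.76,30.39,3
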