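label,thickness_um,mean_velocity_m_s,velocity_sd,mean_modulus_kpa,modulus_sd,n_repeats
0,506,7.69,0.18,177.29,7.77,3
45,473,7.75,0.33,183.11,15.91,3
90,574,7.81,0.33,182.14,15.20,3
135,527,7.77,0.50,180.24,22.46,3
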