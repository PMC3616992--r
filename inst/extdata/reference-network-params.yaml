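.type: apoptosis_params
kact: 0.005
k_bik_bcl2: 0.000105
ktrunc: 0.00014
k_tbid_bcl2: 8.7e-05
k_disp: 0.88
kcat_bax: 0.0104
Km_bax: 114.0
k_dim: 0.000185
k_auto: 0.0144
k_bax_bcl2: 2.1e-05
k_back: 0.007
gamma: 4.15
a: 0.0205
bax_star: 13.0

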