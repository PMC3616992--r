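.type: apoptosis_params
kact: 0.005
k_bik_bcl2: 0.000105
ktrunc: 0.001791234915132
k_tbid_bcl2: 8.7e-05
k_disp: 0.141203199221546
kcat_bax: 0.040012405497257
Km_bax: 141.226739920045986
k_dim: 0.000610408318922
k_auto: 0.085707658325894
k_bax_bcl2: 4.02242972950491e-06
k_back: 7.518385594887381e-05
gamma: 7.90796731846801
a: 0.022258571942605
bax_star: 13.0

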