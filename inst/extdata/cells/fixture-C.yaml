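Cm: 37.0
g_leak: 2.082803761872202
E_leak: -10.0
g_Na: 91.865648488250187
E_Na: 66.700000000000003
V_half_m: -46.0
k_m: 6.0
tau_m: 1.0
V_half_h: -85.0
k_h: 1.0
tau_h: 7.0
g_CaL: 3.89582635574149
E_Ca: 70.0
V_half_d: -5.8
k_d: 10.0
tau_d: 2.0
V_half_f: -35.0
k_f: 5.0
tau_f: 150.0
g_Kr: 3.0
E_Kr: -85.900000000000006
V_half_xr: 10.0
k_xr: 6.0
tau_xr: 300.0
V_half_r: -50.0
k_r: 18.0
g_K1_endo: 20.0
ba_block: 1.0
id: C
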