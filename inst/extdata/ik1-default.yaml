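gK1_density: 400.0
EK: -95.0
Ko: 4.0
Ki: 120.0
temperature: 20.0
Mg_i: 1.0
SPM_i: 5.0
mode1_fraction: 0.9
rate_constants:
  mg_alpha: 12.0
  mg_alpha_slope: -0.025
  mg_beta: 0.28
  mg_beta_slope: 0.025
  mg_sites: 3.0
  spm1_kd0: 0.04
  spm1_kd_slope: 0.10989010989011
  spm2_alpha: 0.68
  spm2_alpha_slope: 0.07
  spm2_alpha_sat: 0.12
  spm2_beta: 1.12
  spm2_beta_slope: 0.15
  spm2_beta_sat: 0.13
  spm2_mg_shift: 8.0
  ko_ref: 4.0
  ko_exponent: 0.4
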