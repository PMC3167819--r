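schema: stemfate-params/1
wnt_signal_curve:
  kind: up
  vmax: 2.0
  half_sat: 1.0
  hill: 2.0
dkk_inhibition_curve:
  kind: down
  vmax: 1.0
  half_sat: 7.45
  hill: 2.0
dkk_synth_curve:
  kind: up
  vmax: 0.005
  half_sat: 0.1
  hill: 2.0
dkk_deg: 0.0145
lef_ecad_curve:
  kind: down
  vmax: 1.0
  half_sat: 1.7
  hill: 2.0
lef_deg: 0.5
ecad_synth_curve:
  kind: down
  vmax: 0.1
  half_sat: 1.2
  hill: 2.0
ecad_deg: 0.1
ecad_binding_coeff: 0.5
pf_synth_curve:
  kind: up
  vmax: 0.1
  half_sat: 0.4
  hill: 2.0
pf_deg: 0.1
notch_synth: 0.1
notch_deg_curve:
  kind: down
  vmax: 0.5
  half_sat: 0.28
  hill: 1.0
hes_synth_curve:
  kind: up
  vmax: 0.2
  half_sat: 0.62
  hill: 6.0
hes_deg: 0.2
df_synth_curve:
  kind: down
  vmax: 0.05
  half_sat: 0.45
  hill: 4.0
df_deg: 0.033333333333333
c_p: 0.54
c_m: 1.1
tau: 24.0
phi: 336.0
dsl_level: 0.12
wnt_ext: 1.0
ng_per_model_unit: 2.01
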