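# Example trichodiel configuration. Every key under `params` overrides one
# registry constant; anything omitted keeps its documented default.
schema_version: 1
params:
  k_O2_NF: 0.005          # mol O2 m^-3, O2 half-inhibition of nitrogenase
  geometry:
    R: 1.0e-5             # cytoplasm radius (m)
    L: 1.0e-3             # trichome length (m)
environment:
  fe_diss: 40             # dissolved inorganic Fe (pM)
  o2_ext: 0.213           # far-field O2 (mol m^-3), air saturation
  light: sine
  i_max: 140              # peak irradiance (umol photons m^-2 s^-1)
  photoperiod: 12         # h
scenarios:
- name: lowfe_dynamic
  mode: dynamic
  fe_diss: 40
- name: lowfe_fixed
  mode: fixed
  fe_diss: 40
- name: highfe_dynamic
  mode: dynamic
  fe_diss: 1250
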