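type: RE
C_m: 1.0
E_L: -60.0
E_KL: -90.0
area_cm2: 0.000143
tau_ca_ms: 100.0
ca_rest_uM: 0.05
densities_mS_cm2:
  Na: 100.0
  DR: 8.0
  CaT: 3.5
  AHP: 0.05
  CAN: 0.05

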