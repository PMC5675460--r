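type: IN
C_m: 1.0
E_L: -60.0
E_KL: -90.0
area_cm2: 0.00017
tau_ca_ms: 10.0
ca_rest_uM: 0.05
densities_mS_cm2:
  Na: 90.0
  DR: 6.0
  H: 0.015
  CaHT: 2.5
  AHP: 0.2
  CAN: 0.05

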