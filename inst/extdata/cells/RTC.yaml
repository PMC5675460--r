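type: RTC
C_m: 1.0
E_L: -70.0
E_KL: -90.0
area_cm2: 0.00029
tau_ca_ms: 10.0
ca_rest_uM: 0.05
densities_mS_cm2:
  Na: 90.0
  DR: 6.0
  CaT: 2.4
  CaHT: 0.6
  CaL: 0.3
  H: 0.05
  AHP: 0.6
  CAN: 0.02

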