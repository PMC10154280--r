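{
  "q10_sco_25": 0.60,
  "q10_sco_35": 0.62,
  "q10_kc_ubar": 2.24,
  "q10_ko_mbar": 1.63
}
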