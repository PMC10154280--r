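[
  {"species": "Cyanidium caldarium",   "Sc_o": 224.6, "Kc_uM": 6.7, "Ko_uM": 374, "T_ref_C": 25},
  {"species": "Galdieria partita",     "Sc_o": 238.1, "Kc_uM": 6.6, "Ko_uM": 374, "T_ref_C": 25},
  {"species": "Galdieria sulphuraria", "Sc_o": 166.0, "Kc_uM": 3.3, "Ko_uM": 374, "T_ref_C": 25}
]
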