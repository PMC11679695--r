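{
  "totals": {"Na": 153.0, "K": 5.4, "Mg": 0.5, "Ca": 1.8, "Cl": 114.4,
             "HCO3": 44.1, "H2PO4": 0.9, "SO4": 0.5},
  "pH": 7.4,
  "temperature_K": 310.15,
  "buffer": "carbonate",
  "tris_mM": 0,
  "albumin_g_per_L": 3.2,
  "albumin_molar_mass": 66400
}
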