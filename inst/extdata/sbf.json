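{
  "totals": {"Na": 142.6, "K": 5.0, "Mg": 1.5, "Ca": 2.6, "Cl": 188.1,
             "HCO3": 5.0, "HPO4": 1.0, "SO4": 0.5},
  "pH": 7.4,
  "temperature_K": 310.15,
  "buffer": "tris",
  "tris_mM": 50,
  "albumin_g_per_L": 0,
  "albumin_molar_mass": 66400
}
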