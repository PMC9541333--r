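{
  "note": "Synthetic anchor-point reconstructions of widely used public-domain chromophore compilations, written from well-known band positions and magnitudes and intended for linear interpolation onto a 1-nm grid. They approximate, but are not digitizations of, the cited sources.",
  "chromophores": {
    "water": {
      "file": "water_synthetic.csv",
      "units": "mua_cm1",
      "description": "Absorption coefficient of pure water, approximating the Hale-Querry (1973) / Kou (1993) compilations.",
      "support_nm": [400, 1600]
    },
    "fat": {
      "file": "fat_synthetic.csv",
      "units": "mua_cm1",
      "description": "Absorption coefficient of purified fat (soybean-oil based), approximating the van Veen (2005) tabulation.",
      "support_nm": [400, 1600]
    },
    "hb_oxy": {
      "file": "hb_oxy_synthetic.csv",
      "units": "molar_extinction_cm1_M",
      "description": "Molar extinction coefficient of oxyhemoglobin, approximating the Prahl compilation. Converted to whole-blood absorption at 150 g/L hemoglobin, MW 64500 g/mol.",
      "support_nm": [400, 1000],
      "reference_concentration_g_per_L": 150,
      "molecular_weight_g_per_mol": 64500
    },
    "hb_deoxy": {
      "file": "hb_deoxy_synthetic.csv",
      "units": "molar_extinction_cm1_M",
      "description": "Molar extinction coefficient of deoxyhemoglobin, approximating the Prahl compilation. Converted to whole-blood absorption at 150 g/L hemoglobin, MW 64500 g/mol.",
      "support_nm": [400, 1000],
      "reference_concentration_g_per_L": 150,
      "molecular_weight_g_per_mol": 64500
    },
    "bilirubin": {
      "file": "bilirubin_synthetic.csv",
      "units": "molar_extinction_cm1_M",
      "description": "Molar extinction coefficient of bilirubin (in chloroform), approximating the Prahl compilation. Converted from mg/dL via MW 584.66 g/mol.",
      "support_nm": [400, 700],
      "molecular_weight_g_per_mol": 584.66
    }
  }
}
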