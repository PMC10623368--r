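{
  "_comment": "Default material property registry. Optical absorption/scattering in mm^-1 (converted to SI on load). Quartz elastic constants are literature fused-quartz values and BegoStone values follow published hard (5:2) phantom characterization; both stand in for unavailable measured data and can be overridden with load_materials().",
  "optical": {
    "water":     { "mu_a": 2.42,  "mu_s": 0.0,  "g": 0.0, "n": 1.33 },
    "vapor":     { "mu_a": 0.001, "mu_s": 0.0,  "g": 0.0, "n": 1.0  },
    "begostone": { "mu_a": 6.0,   "mu_s": 20.0, "g": 0.9, "n": 1.55 }
  },
  "thermal": {
    "water":     { "rho": 998.2, "cp": 4182, "k_cond": 0.598, "melt_T": 373.15, "latent_heat_vap": 2.257e6 },
    "begostone": { "rho": 1995,  "cp": 1100, "k_cond": 1.3,   "melt_T": 1450,   "latent_heat_vap": 2.0e6 }
  },
  "elastic": {
    "quartz":    { "rho": 2200, "c_L": 5970, "c_T": 3760 },
    "begostone": { "rho": 1995, "c_L": 4159, "c_T": 2319 },
    "psm4":      { "rho": 1200, "c_L": 2570, "c_T": 1150 }
  },
  "fluid": {
    "water": { "rho": 998.2, "c": 1480, "p_stat": 101325, "p_v": 2339, "T0": 293.15 }
  }
}
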