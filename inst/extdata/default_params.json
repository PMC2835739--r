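{
  "version": "1.0",
  "comment": "Ecosystem parameters other than phytoplankton traits and forcing. Units: day-1, uM P, mol/mol.",
  "R_NP": 16,
  "nitrification": {
    "k_nh4_no2": 0.03,
    "k_no2_no3": 0.15
  },
  "detritus": {
    "remin_rate": 0.15,
    "export_rate": 0.01
  },
  "grazers": {
    "small": {
      "g_max": 1.0,
      "K_graze": 0.25,
      "assimilation": 0.3,
      "mortality": 0.05,
      "exponent": 2
    },
    "large": {
      "g_max": 0.8,
      "K_graze": 0.3,
      "assimilation": 0.3,
      "mortality": 0.05,
      "exponent": 2
    }
  },
  "initial": {
    "phyto_biomass": 0.001,
    "grazer_biomass": 0.001
  },
  "integration": {
    "rtol": 1e-08,
    "atol": 1e-12,
    "max_step": 2.0,
    "initial_step": 0.01
  }
}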