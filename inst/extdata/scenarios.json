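{
  "version": "1.0",
  "comment": "Named mixed-layer forcing regimes. Units: m, days, degC, W m-2, uM (N,P), nM (Fe), day-1. Phases are day-of-year of the seasonal maximum: PAR peaks at the solstice, SST lags it by ~70 d, the mixed layer is deepest at the end of winter. nutricline_depth/width set the sub-layer NO3/NO2/PO4 gradient seen by entrainment.",
  "scenarios": {
    "tropical_oligotrophic": {
      "mld_mean": 50,
      "mld_amplitude": 10,
      "mld_phase": 60,
      "sst_mean": 26,
      "sst_amplitude": 1.5,
      "sst_phase": 242.5,
      "surface_par_mean": 160,
      "surface_par_amplitude": 30,
      "surface_par_phase": 172,
      "attenuation_k": 0.03,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0.05,
        "NO3": 2,
        "PO4": 0.3,
        "Fe": 1.2
      },
      "background_exchange": 0.003,
      "nutricline_depth": 60,
      "nutricline_width": 20
    },
    "subtropical_seasonal": {
      "mld_mean": 160,
      "mld_amplitude": 140,
      "mld_phase": 60,
      "sst_mean": 18.5,
      "sst_amplitude": 5.5,
      "sst_phase": 242.5,
      "surface_par_mean": 130,
      "surface_par_amplitude": 90,
      "surface_par_phase": 172,
      "attenuation_k": 0.03,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0.1,
        "NO3": 8,
        "PO4": 1.1,
        "Fe": 1.2
      },
      "background_exchange": 0.003,
      "nutricline_depth": 170,
      "nutricline_width": 25
    },
    "temperate": {
      "mld_mean": 220,
      "mld_amplitude": 180,
      "mld_phase": 60,
      "sst_mean": 11,
      "sst_amplitude": 5,
      "sst_phase": 242.5,
      "surface_par_mean": 100,
      "surface_par_amplitude": 80,
      "surface_par_phase": 172,
      "attenuation_k": 0.04,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0.1,
        "NO3": 14,
        "PO4": 1.0,
        "Fe": 1.0
      },
      "background_exchange": 0.003,
      "nutricline_depth": 40,
      "nutricline_width": 20
    },
    "hnlc_iron_limited": {
      "mld_mean": 50,
      "mld_amplitude": 10,
      "mld_phase": 60,
      "sst_mean": 26,
      "sst_amplitude": 1.5,
      "sst_phase": 242.5,
      "surface_par_mean": 160,
      "surface_par_amplitude": 30,
      "surface_par_phase": 172,
      "attenuation_k": 0.03,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0.05,
        "NO3": 8,
        "PO4": 0.3,
        "Fe": 0.06
      },
      "background_exchange": 0.003,
      "nutricline_depth": 60,
      "nutricline_width": 20
    },
    "closed_box": {
      "mld_mean": 50,
      "mld_amplitude": 0,
      "mld_phase": 60,
      "sst_mean": 20,
      "sst_amplitude": 0,
      "sst_phase": 242.5,
      "surface_par_mean": 150,
      "surface_par_amplitude": 0,
      "surface_par_phase": 172,
      "attenuation_k": 0.04,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0.05,
        "NO3": 2,
        "PO4": 0.3,
        "Fe": 1.2
      },
      "background_exchange": 0,
      "nutricline_depth": 0,
      "nutricline_width": 25
    },
    "nh4_only": {
      "mld_mean": 50,
      "mld_amplitude": 10,
      "mld_phase": 60,
      "sst_mean": 26,
      "sst_amplitude": 1.5,
      "sst_phase": 242.5,
      "surface_par_mean": 160,
      "surface_par_amplitude": 30,
      "surface_par_phase": 172,
      "attenuation_k": 0.03,
      "deep_conc": {
        "NH4": 0.1,
        "NO2": 0,
        "NO3": 0,
        "PO4": 0.3,
        "Fe": 1.2
      },
      "background_exchange": 0.003,
      "nutricline_depth": 60,
      "nutricline_width": 20
    }
  }
}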