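{
  "version": "1.0",
  "comment": "Default sampling intervals [low, high] per size class. Calibration choices satisfying the qualitative contracts (small < large for mu_max and N/P half-saturations), not literature values. Units: day-1, degC, W m-2, (W m-2)-1, uM, nM, uM-1, nM/uM.",
  "small": {
    "mu_max": [
      0.4,
      1.0
    ],
    "T_opt": [
      12,
      28
    ],
    "T_width": [
      6,
      12
    ],
    "I_opt": [
      20,
      60
    ],
    "k_inhib": [
      0.0005,
      0.004
    ],
    "K_NH4": [
      0.05,
      0.15
    ],
    "K_NO2": [
      0.06,
      0.2
    ],
    "K_NO3": [
      0.06,
      0.2
    ],
    "K_PO4": [
      0.004,
      0.012
    ],
    "K_Fe": [
      0.1,
      0.3
    ],
    "psi": [
      1.5,
      1.5
    ],
    "R_FeP": [
      1.0,
      2.5
    ],
    "mortality": [
      0.03,
      0.08
    ],
    "palatability": [
      0.8,
      1.0
    ]
  },
  "large": {
    "mu_max": [
      1.1,
      2.5
    ],
    "T_opt": [
      8,
      24
    ],
    "T_width": [
      6,
      12
    ],
    "I_opt": [
      50,
      150
    ],
    "k_inhib": [
      0.0005,
      0.002
    ],
    "K_NH4": [
      0.3,
      0.8
    ],
    "K_NO2": [
      0.35,
      1.0
    ],
    "K_NO3": [
      0.35,
      1.0
    ],
    "K_PO4": [
      0.02,
      0.06
    ],
    "K_Fe": [
      0.4,
      1.0
    ],
    "psi": [
      1.5,
      1.5
    ],
    "R_FeP": [
      1.0,
      2.5
    ],
    "mortality": [
      0.05,
      0.1
    ],
    "palatability": [
      0.8,
      1.0
    ]
  }
}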