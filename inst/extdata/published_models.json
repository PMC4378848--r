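{
  "description": "Published coded-unit regression coefficients for collagen I hydrogel properties. Coded parameters: c_prime = (C-4)/6 (C in mg/ml), t_prime = (T-23)/14 (T in C), ph_prime = pH-7.4, inv_rh_prime = (1/R_H - 1/8.5)/(1/1.4 - 1/8.5) (R_H in nm; printed rounded constants 0.118 and 0.597 correspond to the exact endpoint values used here).",
  "models": {
    "t_half_min": {
      "units": "min",
      "coefficients": {
        "(Intercept)": 21.89,
        "c_prime": -12.69,
        "t_prime": -17.45,
        "c_prime:t_prime": 13.77
      },
      "r_squared": 0.565,
      "notes": "Polymerization half-time; pH not significant."
    },
    "modulus_Pa": {
      "units": "Pa",
      "coefficients": {
        "(Intercept)": -853,
        "c_prime": 5725,
        "t_prime": 2720,
        "ph_prime": 2241
      },
      "r_squared": 0.504,
      "notes": "Confined-compression modulus; main effects only."
    },
    "pore_diameter_um": {
      "units": "um",
      "coefficients": {
        "(Intercept)": 2.236,
        "c_prime": 0.369,
        "t_prime": -0.915,
        "ph_prime": 0.245
      },
      "r_squared": 0.332,
      "notes": "Mean pore diameter; main effects only."
    },
    "diffusivity_um2_s": {
      "units": "um^2/s",
      "coefficients": {
        "(Intercept)": 49.02,
        "c_prime": -21.1,
        "t_prime": -9.33,
        "ph_prime": -5.73,
        "inv_rh_prime": 190.23,
        "ph_prime:inv_rh_prime": 0.37
      },
      "interaction_readings": {
        "as_printed": 0.37,
        "rescaled": 70.3851
      },
      "r_squared": 0.867,
      "notes": "Dextran diffusivity. The ph_prime:inv_rh_prime coefficient is typographically ambiguous at the source: the printed 0.37 equals the normalized sensitivity entry, which would imply an unnormalized coefficient of 0.37*190.23 = 70.3851. Both readings are carried; 'as_printed' is the default."
    }
  }
}
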