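{
  "comment": "Hyperbolic discrimination-curve parameters for Q_IgX(Q_Alb) = (a/b)*sqrt(Q_Alb^2 + b_sq) - c. All values stored as absolute dimensionless fractions: the customary table scalings (b^2 x 10^-6, c x 10^-3, Q_Alb x 10^-3) are already applied.",
  "q_alb_range": [0.002, 0.15],
  "families": {
    "IgG": {
      "upper": {"a_over_b": 0.93, "b_sq": 6e-06, "c": 0.0017},
      "mean":  {"a_over_b": 0.65, "b_sq": 8e-06, "c": 0.0014},
      "lower": {"a_over_b": 0.33, "b_sq": 2e-06, "c": 0.0003}
    },
    "IgA": {
      "upper": {"a_over_b": 0.77, "b_sq": 2.3e-05, "c": 0.0031},
      "mean":  {"a_over_b": 0.47, "b_sq": 2.7e-05, "c": 0.0021},
      "lower": {"a_over_b": 0.17, "b_sq": 7.4e-05, "c": 0.0013}
    },
    "IgM": {
      "upper": {"a_over_b": 0.67, "b_sq": 0.00012, "c": 0.0071},
      "mean":  {"a_over_b": 0.33, "b_sq": 0.000306, "c": 0.0057},
      "lower": {"a_over_b": 0.04, "b_sq": 0.000442, "c": 0.00082}
    }
  },
  "variation_grid": {
    "comment": "Published population variation coefficients (upper - lower)/mean at reference Q_Alb values (Q_Alb stored as absolute fractions). The IgM entry is absent at no grid point here; all three analytes are tabulated at every point.",
    "q_alb": [0.0022, 0.0035, 0.005, 0.0082, 0.01, 0.015, 0.02, 0.05, 0.1, 0.14],
    "IgG": [0.86, 0.89, 0.9, 0.92, 0.91, 0.91, 0.91, 0.92, 0.92, 0.92],
    "IgA": [1.36, 1.41, 1.43, 1.42, 1.4, 1.38, 1.34, 1.31, 1.29, 1.29],
    "IgM": [3.0, 3.0, 3.1, 2.9, 2.9, 2.7, 2.6, 2.2, 2.0, 2.0]
  }
}
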