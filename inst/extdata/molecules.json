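{
  "comment": "Reference molecule specifications. r_h_nm: experimentally measured hydrodynamic radius (IgA: monomeric variant). aleph_fitted: dimensionless exchange coefficient from fitting the connected steady-state model to the mean hyperbolic curves with anchors aleph_albumin = 2, k/L = 1.",
  "molecules": [
    {"name": "Albumin", "r_h_nm": 3.51,  "aleph_fitted": 2.0},
    {"name": "IgG",     "r_h_nm": 5.29,  "aleph_fitted": 1.23},
    {"name": "IgA",     "r_h_nm": 6.50,  "aleph_fitted": 0.86},
    {"name": "IgM",     "r_h_nm": 12.65, "aleph_fitted": 0.55}
  ]
}
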