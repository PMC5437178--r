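# packaged curve families, loaded once per test run
fams <- reibergram_families()

# analyte-indexed printed fitted exchange coefficients (anchor aleph_Alb = 2)
aleph_printed <- c(IgG = 1.23, IgA = 0.86, IgM = 0.55)
rh_nm <- c(Albumin = 3.51, IgG = 5.29, IgA = 6.50, IgM = 12.65)
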