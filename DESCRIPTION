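Package: csfquotient
Title: Connected Steady-State Modelling of Blood-CSF Protein Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the entry of blood-derived proteins into cerebrospinal
    fluid (CSF) as a system of consecutive steady states between
    barrier-restricted diffusion and CSF bulk flow, giving the saturation
    law Q(t) = 1 - exp(-aleph*k*t/L) for CSF/serum concentration quotients.
    Provides the hyperbolic quotient-diagram (Reibergram) reference curves
    for IgG, IgA and IgM with population variation coefficients and
    classification of patient quotients against the discrimination limits;
    least-squares fitting of exchange-coefficient ratios to the empirical
    hyperbolic relations; Stokes-Einstein conversion between exchange
    coefficients, hydrodynamic radii and barrier factors; the rival
    erfc-based molecular-flux model for comparison; physiological transport
    calculators (bulk-flow velocity, Peclet number, residence times) and
    rostrocaudal gradient source classification; and a synthetic patient
    cohort generator for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
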