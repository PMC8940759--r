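Package: gpconv
Title: Gamma-Pareto Type I Convolution Distributions for Heavy-Tailed
    Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation of the gamma-Pareto type I convolution (GPC)
    distribution family used to model intravenous bolus drug disposition
    with a power-function tail: density, cumulative distribution, the
    super-cumulative (integral of the CDF) and the density derivative,
    computed by complementary short-time and long-time series algorithms
    with controlled arbitrary-precision arithmetic (GNU MPFR).  Includes
    the arbitrary-precision special-function building blocks (incomplete
    beta with negative parameter, confluent hypergeometric functions,
    regularised incomplete gamma), a tanh-sinh quadrature oracle for
    validation, multidose superposition with dose-retention accounting,
    proportional-error (1/C^2-weighted) nonlinear regression by
    multi-start Nelder-Mead, model-based residual bootstrap confidence
    intervals, and a synthetic concentration-time data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
SystemRequirements: GNU MPFR (>= 4.0), GNU GMP
NeedsCompilation: yes
Config/testthat/edition: 3
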