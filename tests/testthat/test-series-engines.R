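# Short-t and long-t series engines against the independent tanh-sinh
# quadrature oracle, plus the structural invariants of the two-pass scheme.

test_that("component densities: step convention, normalisation, closed values", {
  expect_equal(pd_pdf(c(0.5, 1) * 0.1, 0.5, 0.1), c(0, 0))
  expect_equal(pd_pdf(0.2, 1, 0.1), 1 / (4 * 0.1), tolerance = 1e-14)
  q <- integrate(gd_pdf, 0, Inf, a = 0.7, b = 2.2, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
})

test_that("density matches the convolution quadrature oracle to >= 30 digits", {
  p <- gpc_params(0.5, 1, 0.5, beta_h = 0.1)
  oracle <- conv_quadrature_oracle(0.3, p, gpc_policy(36))
  engine <- evaluate_short("pdf", 0.3, p, pol40)
  expect_gte(hp_digits_agree(oracle, engine$value), 30)
  # dog-1 parameters at 1 h (long-branch territory, forced both ways)
  o2 <- conv_quadrature_oracle(1, dog1, gpc_policy(36))
  expect_gte(hp_digits_agree(o2, evaluate_short("pdf", 1, dog1, pol40)$value), 30)
  expect_gte(hp_digits_agree(o2, evaluate_long("pdf", 1, dog1, pol40)$value), 30)
  # oracle is zero at and below the delay
  expect_equal(hp_num(conv_quadrature_oracle(0.05, p, pol30)), 0)
})

test_that("oracle agreement holds across a random parameter sweep", {
  ps <- random_params(5, seed = 101)
  set.seed(202)
  for (p in ps) {
    tt <- runif(1, p$beta_h * 1.5, 20 / p$b)
    oracle <- conv_quadrature_oracle(tt, p, gpc_policy(32))
    engine <- gpc_evaluate("pdf", tt, p, gpc_policy(40))
    expect_gte(hp_digits_agree(oracle, engine$value), 25)
  }
})

test_that("CDF and super-cumulative match their independent quadrature routes", {
  p <- gpc_params(0.5, 1, 0.5, beta_h = 0.01)
  oF <- conv_quadrature_oracle(0.5, p, gpc_policy(32), kind = "cdf")
  eF <- gpc_evaluate("cdf", 0.5, p, pol40)
  expect_gte(hp_digits_agree(oF, eF$value), 25)
  oS <- conv_quadrature_oracle(0.5, p, gpc_policy(32), kind = "supercdf")
  eS <- gpc_evaluate("supercdf", 0.5, p, pol40)
  expect_gte(hp_digits_agree(oS, eS$value), 25)
  # and for dog-1 at a long-branch time
  oF2 <- conv_quadrature_oracle(24, dog1, gpc_policy(32), kind = "cdf")
  expect_gte(hp_digits_agree(oF2, gpc_evaluate("cdf", 24, dog1, pol40)$value), 25)
})

test_that("short-t scan: peak bookkeeping near the delay", {
  # just above beta the term magnitudes decrease monotonically, so the
  # largest stored term is the n = 0 term (prefactor included)
  tt <- dog1$beta_h * 1.01
  sc <- scan_short_terms("pdf", tt, dog1, pol65)
  z <- 1 - dog1$beta_h / tt
  first <- hp_num(beta_inc(z, dog1$a, -dog1$alpha, pol30))
  lpref <- dog1$a * log(dog1$b) + log(dog1$alpha) +
    dog1$alpha * log(dog1$beta_h) - lgamma(dog1$a) +
    (dog1$a - dog1$alpha - 1) * log(tt)
  expect_equal(sc$max_term_log10,
               round((lpref + log(abs(first))) / log(10)))
  expect_error(scan_short_terms("pdf", dog1$beta_h / 2, dog1, pol65),
               "exceed")
})

test_that("short-t summand alternates in sign and decays for t < 4 beta", {
  tt <- 3 * dog1$beta_h
  z <- 1 - dog1$beta_h / tt
  bt <- dog1$b * tt
  terms <- vapply(0:8, function(n)
    (-bt)^n / factorial(n) *
      hp_num(beta_inc(z, dog1$a + n, -dog1$alpha, pol30)), 0.0)
  expect_true(all(sign(terms) == (-1)^(0:8)))
  expect_true(all(diff(abs(terms)) < 0))
})

test_that("both branches return exactly zero at and below the delay", {
  for (kind in c("pdf", "cdf", "supercdf", "deriv")) {
    r <- evaluate_short(kind, dog1$beta_h, dog1, pol30)
    expect_equal(hp_num(r$value), 0)
    expect_identical(r$n_terms, 0L)
    expect_equal(hp_num(evaluate_long(kind, dog1$beta_h / 2, dog1, pol30)$value), 0)
  }
})

test_that("forced short and long branches agree to >= 63 digits at overlapping times", {
  # the absolute 1e-65 stopping rule bounds the absolute error while the
  # working precision bounds the relative error, so agreement is measured
  # as the better of decimal places and significant digits
  for (kind in c("pdf", "cdf", "supercdf", "deriv")) {
    for (tt in c(2 * dog1$beta_h, 4 * dog1$beta_h, 1, 12, 72)) {
      s <- evaluate_short(kind, tt, dog1, pol65)
      l <- evaluate_long(kind, tt, dog1, pol65)
      agree <- max(hp_digits_agree(s$value, l$value),
                   hp_places_agree(s$value, l$value))
      expect_gte(agree, 63)
    }
  }
})

test_that("calculus chain: numerical derivatives link deriv, pdf, cdf, supercdf", {
  pol60 <- gpc_policy(60)
  fd <- function(kind, tt) {
    # dyadic step keeps both abscissae exact and exactly symmetric
    h <- 2^-43
    up <- gpc_evaluate(kind, tt + h, dog1, pol60)$value
    dn <- gpc_evaluate(kind, tt - h, dog1, pol60)$value
    hp_div(hp_sub(up, dn, 70), hpnum(2 * h), 70)
  }
  for (tt in c(0.02, 12)) {
    expect_gte(hp_digits_agree(fd("cdf", tt),
                               gpc_evaluate("pdf", tt, dog1, pol60)$value), 20)
    expect_gte(hp_digits_agree(fd("supercdf", tt),
                               gpc_evaluate("cdf", tt, dog1, pol60)$value), 20)
    expect_gte(hp_digits_agree(fd("pdf", tt),
                               gpc_evaluate("deriv", tt, dog1, pol60)$value), 20)
  }
})

test_that("CDF is a proper distribution function with a power-law survival tail", {
  ts <- c(0.05, 0.5, 5, 50, 500)
  Fs <- vapply(ts, function(tt)
    hp_num(gpc_evaluate("cdf", tt, dog1, pol30)$value), 0.0)
  expect_true(all(diff(Fs) > 0))
  expect_true(all(Fs >= 0 & Fs <= 1))
  # survival 1-F ~ C t^-alpha in the far tail: slope check over a decade
  s4 <- 1 - hp_num(gpc_evaluate("cdf", 1e4, dog1, pol30)$value)
  s5 <- 1 - hp_num(gpc_evaluate("cdf", 1e5, dog1, pol30)$value)
  expect_gt(s5, 0)             # tends to 1 but is nowhere near it yet
  expect_equal(log10(s4 / s5), dog1$alpha, tolerance = 0.02)
  # pdf nonnegative, supercdf increasing and convex
  Ss <- vapply(ts, function(tt)
    hp_num(gpc_evaluate("supercdf", tt, dog1, pol30)$value), 0.0)
  expect_true(all(diff(Ss) > 0))
  expect_true(all(diff(diff(Ss)) > 0))
})

test_that("long-t diagnostics at one-half year match the extreme-scale expectations", {
  l <- evaluate_long("pdf", 4396, dog1, pol65)
  expect_identical(l$n_terms, 1L)
  # the only summand term is vanishingly small (order 1e-1403)
  expect_true(l$max_term_log10 < -1380 && l$max_term_log10 > -1420)
  # closed-form part (gamma + asymptote) therefore carries the full value
  gd_part <- gd_pdf(4396, dog1$a, dog1$b)     # ~ e^-3217, utterly negligible
  asym <- asymptote_pdf(4396, dog1, pol65)
  expect_gte(hp_digits_agree(asym, l$value), 64)
  expect_equal(gd_part, 0)
})

test_that("asymptote converges to the density as t grows", {
  # |pdf - asymptote - gamma part| / pdf collapses double-exponentially,
  # far below double resolution, so the residual is formed at 40 digits
  rel <- vapply(c(10, 50, 100), function(tt) {
    f <- gpc_evaluate("pdf", tt, dog1, pol40)$value
    a_ <- asymptote_pdf(tt, dog1, pol40)
    g <- hpnum(gd_pdf(tt, dog1$a, dog1$b))
    abs(hp_num(hp_div(hp_sub(hp_sub(f, a_, 45), g, 45), f, 45)))
  }, 0.0)
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 1e-30)
})

test_that("long-t term ratios decay on the beta/t scale", {
  # each successive simplified term is several hundred times smaller at
  # 12 h: the decay scale is beta/t (with an O(1) factor), so summation
  # may stop on the last term alone
  for (k in 1:5) {
    r <- long_term_ratio(k, 12, dog1)
    expect_lt(r, 4 * dog1$beta_h / 12)
    expect_gt(r, 0)
  }
  # far from the branch point the decay stays on the beta/t-times-bt
  # scale, i.e. a few parts per thousand per term here as well
  for (k in 1:3) expect_lt(long_term_ratio(k, 120, dog1), 0.01)
  # at the 4*beta branch point the next term is at worst about 1/4 of the
  # current one
  for (k in 1:5)
    expect_lte(long_term_ratio(k, 4 * dog1$beta_h, dog1), 0.26)
})

test_that("near-integer alpha and integer a are guarded", {
  expect_error(gpc_params(0.5, 1, 1 + 1e-10, beta_h = 0.01), "integer")
  p_int_a <- gpc_params(1, 1, 0.5, beta_h = 0.001)
  expect_error(evaluate_long("pdf", 1, p_int_a, pol30), "integer")
  # the dispatcher falls back to the (always valid) short branch
  r <- gpc_evaluate("pdf", 1, p_int_a, pol30)
  expect_identical(r$branch, "short")
  o <- conv_quadrature_oracle(1, p_int_a, gpc_policy(32))
  expect_gte(hp_digits_agree(o, r$value), 25)
})
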