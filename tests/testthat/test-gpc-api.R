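# Dispatcher, half-life, peak finding and AUC-scaled concentration.

test_that("dispatcher switches branches at 4 beta and is continuous there", {
  expect_identical(gpc_evaluate("pdf", 3.9 * dog1$beta_h, dog1, pol30)$branch,
                   "short")
  expect_identical(gpc_evaluate("pdf", 4.1 * dog1$beta_h, dog1, pol30)$branch,
                   "long")
  r0 <- gpc_evaluate("pdf", dog1$beta_h / 2, dog1, pol30)
  expect_equal(hp_num(r0$value), 0)
  expect_identical(r0$branch, "short")
  expect_identical(r0$n_terms, 0L)
  eps <- 1e-9
  for (kind in c("pdf", "cdf", "supercdf", "deriv")) {
    lo <- hp_num(gpc_evaluate(kind, 4 * dog1$beta_h - eps, dog1, pol30)$value)
    hi <- hp_num(gpc_evaluate(kind, 4 * dog1$beta_h + eps, dog1, pol30)$value)
    expect_equal(lo, hi, tolerance = 1e-5)
  }
})

test_that("forced branches agree at 12 h to >= 63 significant digits", {
  s <- gpc_evaluate("pdf", 12, dog1, pol65, force_branch = "short")
  l <- gpc_evaluate("pdf", 12, dog1, pol65, force_branch = "long")
  expect_identical(s$branch, "short")
  expect_identical(l$branch, "long")
  expect_gte(hp_digits_agree(s$value, l$value), 63)
})

test_that("fast double path tracks the extended-precision engine", {
  ts <- c(0.01, 0.02, 0.1, 1, 12, 72, 336)
  fast <- dgpc(ts, dog1)
  hp <- vapply(ts, function(tt)
    hp_num(gpc_evaluate("pdf", tt, dog1, pol30)$value), 0.0)
  expect_equal(fast, hp, tolerance = 1e-11)
  fastF <- pgpc(ts, dog1)
  hpF <- vapply(ts, function(tt)
    hp_num(gpc_evaluate("cdf", tt, dog1, pol30)$value), 0.0)
  expect_equal(fastF, hpF, tolerance = 1e-11)
  # the bt > 650 fallback route
  expect_equal(dgpc(1000, dog1),
               hp_num(gpc_evaluate("pdf", 1000, dog1, pol30)$value),
               tolerance = 1e-11)
})

test_that("half-life follows its definition and the exponential closed form", {
  # pure exponential (gamma with a = 1): -ln2 f/f' = ln2/b at any t
  b <- 1.7
  f <- gd_pdf(2, 1, b)
  fp <- (gd_pdf(2 + 1e-7, 1, b) - gd_pdf(2 - 1e-7, 1, b)) / 2e-7
  expect_equal(-log(2) * f / fp, log(2) / b, tolerance = 1e-6)
  # against the quadrature oracle and its numeric derivative at 72 h
  h <- 1e-6
  t1 <- 72 + h; t2 <- 72 - h
  f72 <- conv_quadrature_oracle(72, dog1, pol40)
  fp72 <- hp_div(hp_sub(conv_quadrature_oracle(t1, dog1, pol40),
                        conv_quadrature_oracle(t2, dog1, pol40), 45),
                 hpnum(t1 - t2), 45)
  want <- -log(2) * hp_num(hp_div(f72, fp72, 45))
  expect_equal(half_life(72, dog1, pol30), want, tolerance = 1e-14)
  # sign flips across the density peak
  pk <- find_peak(dog1, pol30)
  expect_gt(half_life(pk$t_peak * 1.05, dog1, pol30), 0)
  expect_lt(half_life(pk$t_peak * 0.95, dog1, pol30), 0)
})

test_that("half-life grows linearly with t in the power-function tail", {
  hl <- vapply(c(1e3, 1e4, 1e5), half_life, 0.0, params = dog1,
               policy = pol30)
  expect_true(all(diff(hl) > 0))
  # the tail is Pareto-like, f ~ t^-(alpha+1), so hl ~ t ln2/(1 + alpha):
  # growth is linear in t and the ratios approach 10 per decade
  expect_equal(hl[2] / hl[1], 10, tolerance = 0.05)
  expect_equal(hl[3] / hl[2], 10, tolerance = 0.05)
  expect_equal(hl[3], 1e5 * log(2) / (1 + dog1$alpha), tolerance = 0.02)
})

test_that("find_peak locates the mode: derivative sign change and grid argmax", {
  pk <- find_peak(dog1, pol30)
  d_lo <- hp_num(gpc_evaluate("deriv", pk$t_peak * (1 - 1e-6), dog1, pol30)$value)
  d_hi <- hp_num(gpc_evaluate("deriv", pk$t_peak * (1 + 1e-6), dog1, pol30)$value)
  expect_gt(d_lo, 0)
  expect_lt(d_hi, 0)
  grid <- seq(dog1$beta_h * (1 + 1e-9), 0.1, length.out = 1e5)
  tg <- grid[which.max(dgpc(grid, dog1))]
  expect_equal(pk$t_peak, tg, tolerance = 2 * (grid[2] - grid[1]) / tg)
})

test_that("one-year density is ~2e-7 of the single-dose peak", {
  pk <- find_peak(dog1, pol30)
  ratio <- hp_num(gpc_evaluate("pdf", 8792, dog1, pol30)$value) /
    hp_num(pk$f_peak)
  expect_gt(ratio, 1.5e-7)
  expect_lt(ratio, 2.5e-7)
})

test_that("concentration is AUC-scaled density with consistent clearance", {
  expect_equal(hp_num(concentration(dog1$beta_h / 2, dog1_model, pol30)), 0)
  c12 <- concentration(12, dog1_model, pol30)
  expect_gte(hp_digits_agree(
    c12, hp_mul(gpc_evaluate("pdf", 12, dog1, pol30)$value,
                hpnum(31.16), 35)), 28)
  # integral of C over (0, T) equals AUC * F(T), via an independent route
  q <- integrate(function(tt) concentration(tt, dog1_model, policy = NULL),
                 0, 100, rel.tol = 1e-10, subdivisions = 500)
  expect_equal(q$value,
               31.16 * hp_num(gpc_evaluate("cdf", 100, dog1, pol30)$value),
               tolerance = 1e-8)
  # CL = dose/AUC in mL/(min kg)
  expect_equal(dog1_model$cl * 1000 / 60, 9.76, tolerance = 0.001)
})
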