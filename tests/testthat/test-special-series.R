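# Arbitrary-precision special-function building blocks.
# Frozen reference values were precomputed with an independent
# high-precision oracle (adaptive quadrature of the defining integrals /
# brute-force direct series at elevated precision), not with this package.

test_that("incomplete beta: boundary values and uniform case", {
  expect_equal(hp_num(beta_inc(0, 2.5, -0.7, pol30)), 0)
  # B_z(1,1) = z
  expect_gte(hp_digits_agree(beta_inc(0.4, 1, 1, pol30), hpnum(0.4)), 29)
  # complete beta B(2,3) = 1/12
  expect_gte(hp_digits_agree(beta_inc(1, 2, 3, pol30),
                             hp_div("1", "12", 40)), 29)
})

test_that("incomplete beta with negative second parameter matches the quadrature oracle", {
  # int_0^z u^1.5 (1-u)^-1.7 du by 60-digit adaptive quadrature, evaluated
  # at the IEEE-double value of z = 0.3 that the call passes down
  frozen <- hpnum("3.01388647713085947209072277058133856550453e-2")
  expect_gte(hp_digits_agree(beta_inc(0.3, 2.5, -0.7, pol40), frozen), 38)
})

test_that("incomplete beta routes agree pairwise on random admissible inputs", {
  set.seed(11)
  for (i in 1:6) {
    # dyadic z and A keep 1-z and A+1 exact in double arithmetic, so the
    # three routes are evaluated at identical points
    z <- sample(3:61, 1) / 64
    A <- sample(c(sample(10:128, 1) / 32), 1)
    B <- sample(c(sample(8:96, 1) / 32, -sample(4:28, 1) / 32), 1)
    direct <- beta_inc(z, A, B, pol40, route = "series")
    refl <- beta_inc_reflect(1 - z, A, B, pol40)
    expect_gte(hp_digits_agree(direct, refl), pol40$target_digits - 3)
    # integration-by-parts identity route
    ibp <- beta_ibp_reduce(z, A, B, pol40)
    via <- beta_inc(z, A + 1, B, pol40)
    expect_gte(hp_digits_agree(ibp, via), pol40$target_digits - 4)
  }
})

test_that("integration-by-parts identity reproduces closed forms and guards A+B=0", {
  # B_z(2,1) = z^2/2 at a dyadic z (exact in double)
  got <- beta_ibp_reduce(0.375, 1, 1, pol30)
  want <- hp_div(hp_mul(hpnum("0.375"), hpnum("0.375"), 40), "2", 40)
  expect_gte(hp_digits_agree(got, want), 28)
  expect_error(beta_ibp_reduce(0.5, 1, -1, pol30), "zero")
})

test_that("reflection at the symmetric point and at z = 1", {
  expect_equal(hp_num(beta_inc_reflect(1, 2, 0.5, pol30)), 0)
  expect_gte(hp_digits_agree(beta_inc_reflect(0.5, 0.5, 0.5, pol40),
                             beta_inc(0.5, 0.5, 0.5, pol40)),
             pol40$target_digits - 2)
  # negative-parameter cross-route case
  expect_gte(hp_digits_agree(beta_inc_reflect(0.1, 1.35, -0.2644, pol65),
                             beta_inc(0.9, 1.35, -0.2644, pol65)), 60)
})

test_that("beta_inc is nondecreasing in z for positive B", {
  zs <- seq(0.05, 0.95, by = 0.15)
  vals <- vapply(zs, function(z) hp_num(beta_inc(z, 0.7, 1.3, pol30)), 0.0)
  expect_true(all(diff(vals) > 0))
})

test_that("beta_inc rejects invalid domains", {
  expect_error(beta_inc(-0.1, 1, 1, pol30), "\\[0, 1\\]")
  expect_error(beta_inc(1.1, 1, 1, pol30), "\\[0, 1\\]")
  expect_error(beta_inc(1, 2, -1, pol30), "pole")
})

test_that("Kummer 1F1: trivial values and the cancellation-safe contract", {
  expect_gte(hp_digits_agree(hyp1f1(0.3, 0.7, 0, pol30), hpnum("1")), 29)
  # 1F1(a,a,x) = e^x (frozen 40-digit value of e^3)
  e3 <- hpnum("20.08553692318766774092852965458171789698790")
  expect_gte(hp_digits_agree(hyp1f1(0.55, 0.55, 3, pol40), e3), 38)
  # terminating Kummer route at large negative argument vs frozen
  # brute-force direct series (170-digit working precision oracle); dyadic
  # A keeps B - A = -3 exact, which matters because 1F1 is violently
  # ill-conditioned in B at large negative x
  frozen <- hpnum("1.0542700308352800488980801793454134500398410632165543111e-38")
  got <- hyp1f1(0.25, 0.25 - 3, -100, gpc_policy(55))
  expect_gte(hp_digits_agree(got, frozen), 50)
  # in-package dual route: terminating vs direct elevated-precision series
  direct <- hyp1f1(0.25, 0.25 - 3, -100, gpc_policy(55), method = "direct")
  expect_gte(hp_digits_agree(got, direct), 50)
})

test_that("regularized 1F1 is continuous across nonpositive-integer B", {
  expect_gte(hp_digits_agree(hyp1f1_reg(0.4, 2, 1.3, pol30),
                             hyp1f1(0.4, 2, 1.3, pol30)), 28)
  # frozen oracle value for the asymptote-style argument (at the
  # double-precision parameter values the call passes down)
  frozen <- hpnum("-2.600174369956578877235869418689661147992e-2")
  got <- hyp1f1_reg(0.2644 + 0.3493, 0.3493 - 0.2644, -50, pol40)
  expect_gte(hp_digits_agree(got, frozen), 36)
  # B a nonpositive integer is finite for the regularized form
  v0 <- hp_num(hyp1f1_reg(0.4, 0, 2, pol30))
  expect_true(is.finite(v0))
  # continuity: approach B = 0 along small offsets
  vn <- hp_num(hyp1f1_reg(0.4, 1e-9, 2, pol30))
  expect_lt(abs(vn - v0) / abs(v0), 1e-7)
  expect_error(hyp1f1(0.4, -2, 1, pol30), "pole")
})

test_that("regularized upper incomplete gamma", {
  expect_equal(hp_num(gamma_reg_Q(0.7, 0, pol30)), 1)
  # Q(1,x) = exp(-x)
  expect_gte(hp_digits_agree(gamma_reg_Q(1, 2.25, pol40),
                             hyp1f1(1, 1, -2.25, pol40)), 38)
  # frozen quadrature oracle value (at the double value of a = 0.3493)
  frozen <- hpnum("1.472247125784630298850298473429089724683e-2")
  expect_gte(hp_digits_agree(gamma_reg_Q(0.3493, 2.5, pol40), frozen), 36)
  # complementarity against the independent double-precision implementation
  for (x in c(0.1, 1, 5, 40)) {
    expect_equal(hp_num(gamma_reg_Q(0.3493, x, pol30)),
                 stats::pgamma(x, 0.3493, lower.tail = FALSE),
                 tolerance = 1e-13)
  }
  # monotone nonincreasing in x
  xs <- c(0, 0.5, 1, 2, 4, 8, 16)
  qs <- vapply(xs, function(x) hp_num(gamma_reg_Q(0.3493, x, pol30)), 0.0)
  expect_true(all(diff(qs) < 0))
  expect_error(gamma_reg_Q(-1, 1, pol30), "a must be")
  expect_error(gamma_reg_Q(1, -1, pol30), "x must be")
})

test_that("Pochhammer symbol", {
  expect_equal(hp_num(pochhammer(2.7, 0)), 1)
  expect_equal(hp_num(pochhammer(1, 6)), factorial(6))
  expect_equal(hp_num(pochhammer(0.6507, 3)), 0.6507 * 1.6507 * 2.6507,
               tolerance = 1e-14)
  expect_error(pochhammer(1, -1), "nonnegative")
})

test_that("high-precision string helpers behave", {
  expect_equal(hp_digits_agree("1.0000000000", "1.0000000000"), Inf)
  expect_equal(hp_digits_agree("1.234567", "1.234599"), 4)
  expect_equal(hp_num(hp_sum(c("1e-30", "1", "-1"), digits = 45)), 1e-30)
})
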