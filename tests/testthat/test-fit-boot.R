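# Proportional-error fitting, bootstrap machinery and the CI/CV helpers.

test_that("rrms loss: exact fit gives 0, uniform 10% error gives exactly 0.10", {
  ts <- c(0.5, 1, 2, 4, 8, 24, 48, 72)
  exact <- conc_series(ts, 31.16 * dgpc(ts, dog1))
  expect_equal(rrms_loss(dog1_model, exact), 0)
  # predictions exactly 1.1x the data: rrms = 0.10 by construction
  deflated <- conc_series(ts, 31.16 * dgpc(ts, dog1) / 1.1)
  expect_equal(rrms_loss(dog1_model, deflated), 0.10, tolerance = 1e-12)
  expect_error(conc_series(ts, rep(0, length(ts))), "> 0")
})

test_that("noise-free synthetic data is recovered to >= 4 significant digits", {
  d <- generate_synthetic(dog1_model, synth_design(noise_rrms = 0, seed = 5))
  f <- fit_gpc(d, dose = 18.248, seed = 2, n_starts = 8, maxit = 3000)
  expect_lt(f$rrms, 1e-8)
  truth <- c(a = 0.3493, b = 0.7318, alpha = 0.2644, auc = 31.16)
  for (p in names(truth)) {
    got <- if (p == "auc") f$auc else f$theta[[p]]
    expect_lt(abs(got - truth[[p]]) / truth[[p]], 5e-5)
  }
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("hp and fast objective routes land on the same optimum", {
  d <- generate_synthetic(dog1_model, synth_design(seed = 31))
  ff <- fit_gpc(d, seed = 4, n_starts = 2, maxit = 400)
  fh <- fit_gpc(d, seed = 4, n_starts = 2, maxit = 400, eval = "hp",
                eval_digits = 25)
  expect_equal(ff$theta, fh$theta, tolerance = 1e-6)
  expect_equal(ff$rrms, fh$rrms, tolerance = 1e-8)
})

test_that("fitting is invariant to uniform concentration rescaling", {
  d <- generate_synthetic(dog1_model, synth_design(seed = 12))
  f1 <- fit_gpc(d, seed = 6, n_starts = 3)
  d2 <- conc_series(d$times, d$concs * 1.25)
  f2 <- fit_gpc(d2, seed = 6, n_starts = 3)
  expect_equal(f2$auc / f1$auc, 1.25, tolerance = 0.02)
  for (p in c("a", "b", "alpha"))
    expect_equal(f2$theta[[p]], f1$theta[[p]], tolerance = 0.02)
  expect_equal(f1$rrms, f2$rrms, tolerance = 1e-4)
})

test_that("seeded fits and bootstraps are reproducible", {
  d <- generate_synthetic(dog1_model, synth_design(seed = 77))
  f1 <- fit_gpc(d, dose = 18.248, seed = 9, n_starts = 2)
  f2 <- fit_gpc(d, dose = 18.248, seed = 9, n_starts = 2)
  expect_identical(f1$theta, f2$theta)
  b1 <- bootstrap_gpc(d, f1, n_reps = 6, seed = 3)
  b2 <- bootstrap_gpc(d, f1, n_reps = 6, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("bootstrap degenerates correctly on zero-residual data", {
  ts <- exp(seq(log(1 / 3), log(72), length.out = 21))
  d0 <- conc_series(ts, 31.16 * dgpc(ts, dog1))
  f0 <- fit_gpc(d0, dose = 18.248, seed = 1, n_starts = 3, maxit = 1500)
  # data that the fitted model reproduces exactly: residuals are all 1,
  # every resampled data set is the original, every refit is identical
  d1 <- conc_series(ts, f0$auc * dgpc(ts, f0$params))
  bb <- bootstrap_gpc(d1, f0, n_reps = 4, seed = 2)
  for (p in c("a", "b", "alpha", "auc"))
    expect_identical(max(abs(bb$replicates[[p]] - bb$replicates[[p]][1])), 0)
  expect_error(bootstrap_gpc(d1, f0, n_reps = 0), "positive")
})

test_that("bootstrap summary reports screens and coherent intervals", {
  d <- generate_synthetic(dog1_model, synth_design(seed = 21))
  f <- fit_gpc(d, dose = 18.248, seed = 5, n_starts = 2)
  bb <- bootstrap_gpc(d, f, n_reps = 10, seed = 7)
  expect_true(is.finite(bb$screens$shapiro_p))
  s <- bb$summary
  expect_true(all(s$ci_t_lo <= s$mean & s$mean <= s$ci_t_hi))
  med <- vapply(s$parameter, function(p) median(bb$replicates[[p]]), 0.0)
  expect_true(all(s$ci_q_lo <= med & med <= s$ci_q_hi))
})

test_that("Student-t interval with df = n matches the closed form", {
  got <- ci_student_t(c(0, 1), level = 0.95, df_mode = "n")
  half <- 4.30265272991 * sd(c(0, 1)) / sqrt(2)
  expect_equal(got, c(0.5 - half, 0.5 + half), tolerance = 1e-9)
  expect_equal(ci_student_t(c(2, 2, 2), level = 0.9), c(2, 2))
  expect_error(ci_student_t(1), "at least 2")
  # df = n vs n-1 hardly matters at n = 40
  set.seed(8)
  v <- rnorm(40)
  w_n <- diff(ci_student_t(v, df_mode = "n"))
  w_n1 <- diff(ci_student_t(v, df_mode = "n-1"))
  expect_lt(abs(w_n / w_n1 - 1), 0.003)
})

test_that("Weibull plotting-position quantile interval", {
  expect_equal(ci_quantile_weibull(1:40, level = 0), c(20.5, 20.5))
  expect_equal(ci_quantile_weibull(c(1, 2, 3), level = 0), c(2, 2))
  set.seed(99)
  u <- runif(1e4)
  ci <- ci_quantile_weibull(u, level = 0.95)
  expect_equal(ci[1], 0.025, tolerance = 0.01 / 0.025)
  expect_equal(ci[2], 0.975, tolerance = 0.01 / 0.975)
  # clamped with a warning when the tail probabilities are unreachable
  expect_warning(ci_quantile_weibull(1:5, level = 0.99), "clamped")
  # hand-rolled i/(n+1) interpolation agrees with the implementation
  set.seed(100)
  v <- rnorm(25)
  sv <- sort(v)
  p <- seq_along(sv) / (length(sv) + 1)
  want <- approx(p, sv, xout = c(0.1, 0.9))$y
  got <- c(ci_quantile_weibull(v, level = 0.8))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("CV summaries: closed forms and the median-of-groups rule", {
  expect_equal(cv_summary(cbind(x = rep(3, 5)))$cv, 0)
  expect_equal(cv_summary(cbind(x = c(9, 11)))$cv, sd(c(9, 11)) / 10,
               tolerance = 1e-12)
  # lognormal: CV -> sqrt(exp(sigma^2)-1) = 0.2227 at sigma = 0.22
  set.seed(13)
  groups <- rep(seq_len(400), each = 35)
  v <- exp(rnorm(400 * 35, 0, 0.22))
  s <- cv_summary(cbind(lognormal = v), groups = groups)
  expect_equal(s$cv_median_groups, sqrt(exp(0.22^2) - 1), tolerance = 0.03)
  # near-zero mean flagged unstable
  set.seed(14)
  s0 <- cv_summary(cbind(z = rnorm(50)))
  expect_true(s0$unstable)
  expect_true(is.na(s0$cv))
  expect_error(cv_summary(cbind(x = 1)), "at least 2")
})

test_that("synthetic noise level is recovered by the relative loss at truth", {
  # rrms at the true parameters estimates the injected noise level
  vals <- vapply(1:200, function(s) {
    d <- generate_synthetic(dog1_model, synth_design(seed = 1000 + s))
    rrms_loss(dog1_model, d)
  }, 0.0)
  expect_equal(mean(vals), 0.086, tolerance = 0.05)
  expect_equal(median(vals), 0.086, tolerance = 0.06)
})
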