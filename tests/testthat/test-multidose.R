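# Multidose superposition: concentration curves, dose-retention
# accounting and interval statistics.  The printed study numbers live in
# the acceptance suite; here the structural identities are checked.

reg14 <- dose_regimen(24, 14)

test_that("single-dose regimen reduces to the plain concentration", {
  reg1 <- dose_regimen(24, 1)
  for (tt in c(0.5, 3, 20)) {
    expect_equal(conc_multidose(tt, dog1_model, reg1, pol30),
                 hp_num(concentration(tt, dog1_model, pol30)),
                 tolerance = 1e-12)
  }
  expect_equal(conc_multidose(dog1$beta_h * 0.9, dog1_model, reg1, pol30), 0)
})

test_that("retention jumps by exactly one dose at dose times", {
  right <- doses_retained(24, dog1, reg14, pol30, side = "right")
  left <- doses_retained(24, dog1, reg14, pol30, side = "left")
  expect_equal(right - left, 1, tolerance = 1e-12)
  expect_equal(doses_retained(0, dog1, reg14, pol30, side = "right"), 1)
  expect_equal(doses_retained(-1, dog1, reg14, pol30), 0)
})

test_that("retained plus eliminated dose-equivalents are conserved", {
  # high-precision retention against the independent fast-path CDF sums
  for (tt in c(10, 36.5, 100, 335)) {
    given <- reg14$dose_times[reg14$dose_times <= tt]
    retained <- doses_retained(tt, dog1, reg14, pol30)
    eliminated <- sum(pgpc(tt - given, dog1))
    expect_equal(retained + eliminated, length(given), tolerance = 1e-11)
  }
})

test_that("interval means via the super-cumulative match direct quadrature", {
  # per-dose identity: integral of (1-F) over (0,x) = x - supercdf(x)
  x <- 24
  q <- integrate(function(u) 1 - pgpc(u, dog1), 0, x, rel.tol = 1e-12)
  expect_equal(q$value,
               x - hp_num(gpc_evaluate("supercdf", x, dog1, pol30)$value),
               tolerance = 1e-9)
  # superposed interval mean vs quadrature of the retention curve
  st <- interval_stats(dog1_model, reg14, 3, pol30)
  q3 <- integrate(function(u) doses_retained(u, dog1, reg14, policy = NULL),
                  48, 72, rel.tol = 1e-11)
  expect_equal(st$mean_retained, q3$value / 24, tolerance = 1e-8)
})

test_that("interval statistics are internally ordered", {
  st <- interval_stats(dog1_model, reg14, 5, pol30)
  expect_lt(st$trough_retained, st$peak_retained)
  expect_gt(st$mean_retained, st$trough_retained)
  expect_lt(st$mean_retained, st$peak_retained)
  expect_equal(st$mean_retained + st$mean_eliminated, 5, tolerance = 1e-12)
  expect_gt(st$peak_conc, st$trough_conc)
  expect_error(interval_stats(dog1_model, reg14, 15, pol30), "range")
  expect_error(interval_stats(dog1_model, reg14, 0, pol30), "range")
})

test_that("trough retention increases toward a bounded accumulation limit", {
  troughs <- vapply(1:14, function(i)
    doses_retained(24 * i, dog1, reg14, pol30, side = "left"), 0.0)
  expect_true(all(diff(troughs) > 0))
  bound <- sum(1 - pgpc(24 * (1:200), dog1))
  expect_true(all(troughs < bound + 1e-9))
})

test_that("accumulation summary needs at least two doses", {
  expect_error(accumulation_summary(dog1_model, dose_regimen(24, 1), pol30),
               "at least 2")
})

test_that("trajectory export has the documented columns and is finite", {
  tr <- multidose_trajectory(dog1_model, dose_regimen(24, 3),
                             times = seq(0, 72, by = 2))
  expect_named(tr, c("t_h", "conc_mg_L", "doses_retained"))
  expect_true(all(is.finite(tr$conc_mg_L)))
  expect_true(all(tr$doses_retained >= 0 & tr$doses_retained <= 3))
})
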