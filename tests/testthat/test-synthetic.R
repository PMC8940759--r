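# Synthetic-data generator, CSV round-tripping and the command-line front
# end.

test_that("generator reproduces the design and is seed-deterministic", {
  d1 <- generate_synthetic(dog1_model, synth_design(seed = 42))
  d2 <- generate_synthetic(dog1_model, synth_design(seed = 42))
  expect_identical(d1$times, d2$times)
  expect_identical(d1$concs, d2$concs)
  expect_length(d1$times, 21)
  expect_true(all(d1$times >= 1 / 3 - 1e-9 & d1$times <= 72 + 1e-6))
  expect_true(all(diff(d1$times) > 0))
  d3 <- generate_synthetic(dog1_model, synth_design(seed = 43))
  expect_false(identical(d1$concs, d3$concs))
})

test_that("zero noise returns the exact model curve", {
  d <- generate_synthetic(dog1_model, synth_design(noise_rrms = 0, seed = 3))
  expect_equal(d$concs, 31.16 * dgpc(d$times, dog1), tolerance = 1e-14)
})

test_that("noise calibration: empirical rms relative error matches the design", {
  errs <- unlist(lapply(1:400, function(s) {
    d <- generate_synthetic(dog1_model, synth_design(seed = 4000 + s))
    d$concs / (31.16 * dgpc(d$times, dog1)) - 1
  }))
  expect_equal(sqrt(mean(errs^2)), 0.086, tolerance = 0.025)
})

test_that("design guards its domain", {
  expect_error(generate_synthetic(dog1_model, synth_design(t_min = 1e-4)),
               "beta")
  expect_error(synth_design(n_samples = 1), "n_samples")
  expect_error(synth_design(noise_rrms = -0.1), "noise_rrms")
})

test_that("concentration CSV round-trips exactly", {
  d <- generate_synthetic(dog1_model, synth_design(seed = 17))
  path <- tempfile(fileext = ".csv")
  write_concentration_csv(d, path)
  d2 <- read_concentration_csv(path)
  expect_identical(d$times, d2$times)
  expect_identical(d$concs, d2$concs)
  unlink(path)
  expect_error(read_concentration_csv(
    {p <- tempfile(fileext = ".csv"); write.csv(data.frame(x = 1), p); p}),
    "time_h")
})

test_that("command-line front end evaluates and reports diagnostics", {
  cli <- system.file("cli", "gpconv.R", package = "gpconv")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  base <- c(cli, "eval", "--a", "0.3493", "--b", "0.7318",
            "--alpha", "0.2644", "--beta-seconds", "25")
  # below the delay: exact zero, short branch, no terms
  out <- system2(rscript, c(base, "--t-hours", "0.001", "--diagnostics"),
                 stdout = TRUE)
  expect_match(out[1], "^0\\.0*(e\\+?-?0*)?")
  expect_match(out[2], "branch=short n_terms=0")
  # diagnostics equal the library result at 12 h
  out12 <- system2(rscript, c(base, "--t-hours", "12", "--digits", "30",
                              "--diagnostics"), stdout = TRUE)
  r <- gpc_evaluate("pdf", 12, dog1, pol30)
  expect_identical(out12[1], unclass(r$value))
  expect_match(out12[2], sprintf("branch=%s n_terms=%d", r$branch, r$n_terms),
               fixed = TRUE)
})
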