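# Shared fixtures: the dog-1 metformin parameter set (table-rounded) and
# the policies used throughout the suite.
dog1 <- gpc_params(a = 0.3493, b = 0.7318, alpha = 0.2644, beta_s = 25)
dog1_model <- gpc_model(dog1, auc = 31.16, dose = 18.248)
pol30 <- gpc_policy(30)
pol40 <- gpc_policy(40)
pol65 <- gpc_policy(65)

hp_num <- function(x) as.numeric(x)

# random admissible parameter sets for property sweeps
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    alpha <- runif(1, 0.1, 1.9)
    while (abs(alpha - round(alpha)) < 0.02) alpha <- runif(1, 0.1, 1.9)
    gpc_params(a = runif(1, 0.2, 1.2), b = runif(1, 0.3, 25),
               alpha = alpha, beta_h = runif(1, 1e-3, 1e-2))
  })
}
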