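#' Evaluate GPC functions with automatic branch dispatch
#'
#' The public evaluation surface: for \eqn{t \le \beta} every function is
#' exactly zero (step convention); for \eqn{\beta < t < 4\beta} the
#' short-time series converges in a handful of terms; from
#' \eqn{t = 4\beta} on the long-time algorithm is used, where the
#' worst-case next-term ratio is about 1/4 and shrinks like
#' \eqn{\beta/(kt)}.  Either branch may be forced; values agree to
#' approximately the target precision wherever both converge.  When the
#' gamma shape \code{a} sits numerically on an integer the long-time terms
#' hit poles, and the dispatcher falls back to the (always valid)
#' short-time branch.
#'
#' @param kind \code{"pdf"} (1/h), \code{"cdf"} (dimensionless),
#'   \code{"supercdf"} (hours) or \code{"deriv"} (1/h^2).
#' @param t time in hours (scalar; see [dgpc()] for fast vectorized
#'   doubles).
#' @param params a [gpc_params] object.
#' @param policy a [gpc_policy] or digit count.
#' @param force_branch \code{"auto"}, \code{"short"} or \code{"long"}.
#' @return A \code{"gpc_eval"} object (value as [hpnum] plus diagnostics).
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' gpc_evaluate("pdf", 12, dog1, gpc_policy(30))
#' @export
gpc_evaluate <- function(kind, t, params, policy = gpc_policy(),
                         force_branch = "auto") {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  force_branch <- match.arg(force_branch, c("auto", "short", "long"))
  branch <- switch(force_branch,
    short = "short",
    long = "long",
    auto = {
      if (t < 4 * params$beta_h) "short"
      else if (abs(params$a - round(params$a)) < 1e-10) "short"
      else "long"
    })
  if (branch == "short") evaluate_short(kind, t, params, policy)
  else evaluate_long(kind, t, params, policy)
}

#' Fast double-precision GPC functions
#'
#' Vectorized density and CDF in plain doubles (about 13 significant
#' digits at pharmacokinetic sample times), used by the regression loss,
#' the simulation studies and trajectory export.  Same series as the
#' extended-precision engines, automatically dispatched at \eqn{4\beta};
#' when \eqn{e^{bt}} would overflow a double the extended-precision
#' engine takes over behind the scenes.
#'
#' @param t times in hours (vector).
#' @param params a [gpc_params] object.
#' @return Numeric vector.
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' dgpc(c(1, 12, 72), dog1)
#' @export
dgpc <- function(t, params) {
  stopifnot(inherits(params, "gpc_params"))
  .Call(C_gpc_fast, 0L, as.numeric(t), params$a, params$b, params$alpha,
        params$beta_h)
}

#' @rdname dgpc
#' @export
pgpc <- function(t, params) {
  stopifnot(inherits(params, "gpc_params"))
  .Call(C_gpc_fast, 1L, as.numeric(t), params$a, params$b, params$alpha,
        params$beta_h)
}

#' Local disposition half-life
#'
#' The instantaneous exponential-equivalent half-life
#' \eqn{t_{1/2}(t) = -\ln 2 \, f(t)/f'(t)}: positive wherever the density
#' is falling, infinite at the density peak (where \eqn{f'=0}), and for a
#' power-function tail it grows linearly in \eqn{t} instead of settling
#' at a terminal constant.
#'
#' @inheritParams gpc_evaluate
#' @return Half-life in hours (double).
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' half_life(72, dog1, gpc_policy(30))
#' @export
half_life <- function(t, params, policy = gpc_policy(30)) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  if (t <= params$beta_h) stop("t must exceed the delay beta")
  f <- gpc_evaluate("pdf", t, params, policy)
  fp <- gpc_evaluate("deriv", t, params, policy)
  fpn <- as.numeric(fp)
  if (fpn == 0) stop("f'(t) = 0: half-life singular at the density peak")
  r <- hp_div(f$value, fp$value, digits = policy$target_digits)
  -log(2) * as.numeric(r)
}

#' Locate the density peak
#'
#' Bisection on the sign of the derivative over the bracket
#' \eqn{(\beta(1+10^{-6}),\ a/b + 10/b)}; precision-safe at arbitrary
#' digits because only signs of exact evaluations are used.
#'
#' @inheritParams gpc_evaluate
#' @param rel_tol relative tolerance on the peak location.
#' @return List with \code{t_peak} (hours, double) and \code{f_peak}
#'   (1/h, [hpnum]).
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' find_peak(dog1, gpc_policy(30))
#' @export
find_peak <- function(params, policy = gpc_policy(30), rel_tol = 1e-12) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  lo <- params$beta_h * (1 + 1e-6)
  hi <- params$a / params$b + 10 / params$b
  dsign <- function(tt)
    sign(as.numeric(gpc_evaluate("deriv", tt, params, policy)))
  slo <- dsign(lo); shi <- dsign(hi)
  if (slo <= 0 || shi >= 0)
    stop("no derivative sign change in the bracket (beta, a/b + 10/b)")
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (dsign(mid) > 0) lo <- mid else hi <- mid
  }
  t_peak <- (lo + hi) / 2
  list(t_peak = t_peak,
       f_peak = gpc_evaluate("pdf", t_peak, params, policy)$value)
}

#' Single-dose serum concentration
#'
#' \eqn{C(t) = AUC \cdot f(t)} for a [gpc_model]; its integral over
#' \eqn{(0,\infty)} is the model's AUC.
#'
#' @param t time in hours (scalar for the high-precision route).
#' @param model a [gpc_model].
#' @param policy a [gpc_policy]; \code{NULL} uses the fast double path.
#' @return mg/L; [hpnum] under a policy, double under \code{policy = NULL}
#'   (vectorized).
#' @export
concentration <- function(t, model, policy = NULL) {
  stopifnot(inherits(model, "gpc_model"))
  if (is.null(policy)) return(model$auc * dgpc(t, model$params))
  policy <- as_policy(policy)
  f <- gpc_evaluate("pdf", t, model$params, policy)
  hp_mul(f$value, hpnum(model$auc), digits = policy$target_digits)
}
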