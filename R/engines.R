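#' Gamma and Pareto type I component densities
#'
#' The two convolands of the GPC: the gamma density
#' \eqn{e^{-bt}(bt)^a/(t\,\Gamma(a))} for \eqn{t>0} and the Pareto type I
#' density \eqn{(\alpha/t)(\beta/t)^\alpha} for \eqn{t>\beta} (zero
#' otherwise; the unit step convention is \eqn{\theta(x)=0} for
#' \eqn{x \le 0}).
#'
#' @param t time(s) in hours; vectorized.
#' @param a,b gamma shape and rate (1/h).
#' @param alpha,beta_h Pareto shape and delay (hours).
#' @return Numeric vector of densities (1/h).
#' @export
gd_pdf <- function(t, a, b) {
  stopifnot(a > 0, b > 0)
  ifelse(t > 0, exp(-b * t + a * log(b * t) - log(t) - lgamma(a)), 0)
}

#' @rdname gd_pdf
#' @export
pd_pdf <- function(t, alpha, beta_h) {
  stopifnot(alpha > 0, beta_h > 0)
  ifelse(t > beta_h, (alpha / t) * (beta_h / t)^alpha, 0)
}

#' High-precision quadrature oracle for the GPC convolution integral
#'
#' Evaluates the defining convolution
#' \eqn{\int_\beta^t GD(t-\tau)\,PD(\tau)\,d\tau} (and, for
#' \code{kind = "cdf"} / \code{"supercdf"}, the equivalent single
#' integrals obtained by folding the gamma kernel into regularised
#' incomplete gamma functions) by tanh-sinh quadrature at the policy's
#' precision.  This route never touches the series engines, so it serves
#' as an independent oracle for them.
#'
#' @param t time in hours.
#' @param params a [gpc_params] object.
#' @param policy a [gpc_policy]; \code{target_digits} sets the quadrature
#'   goal (30+ digits is routine).
#' @param kind \code{"pdf"}, \code{"cdf"} or \code{"supercdf"}.
#' @return An [hpnum] scalar with attribute \code{"est_digits"}, the
#'   self-convergence estimate of correct digits.
#' @examples
#' p <- gpc_params(0.5, 1, 0.5, beta_h = 0.1)
#' conv_quadrature_oracle(0.3, p, gpc_policy(30))
#' @export
conv_quadrature_oracle <- function(t, params, policy = gpc_policy(40),
                                   kind = "pdf") {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  kind <- match.arg(kind, c("pdf", "cdf", "supercdf"))
  which <- c(pdf = 0L, cdf = 1L, supercdf = 2L)[[kind]]
  r <- .Call(C_conv_quad, as.numeric(t), params$a, params$b, params$alpha,
             params$beta_h, policy$target_digits, which)
  est <- r[[2]]
  if (is.finite(est) && est < policy$target_digits)
    warning(sprintf("quadrature self-estimate is %.0f digits (%d requested)",
                    est, as.integer(policy$target_digits)))
  structure(hpnum(r[[1]]), est_digits = est)
}

#' Scan the short-time summand (pass 1 of the two-pass scheme)
#'
#' Evaluates the magnitude of every term of the short-time series in
#' machine-precision log arithmetic, returning how many terms must be
#' summed (stopping once the magnitude sequence has peaked and the current
#' term falls below \code{10^stop_exponent}) and the base-10 exponent of
#' the largest term.  The required working precision of the second pass is
#' \code{max_term_log10 + target_digits}.
#'
#' @inheritParams conv_quadrature_oracle
#' @param kind one of \code{"pdf"}, \code{"cdf"}, \code{"supercdf"},
#'   \code{"deriv"}.
#' @return List with \code{n_terms} and \code{max_term_log10}.
#' @export
scan_short_terms <- function(kind, t, params, policy = gpc_policy()) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  if (t <= params$beta_h) stop("t must exceed the delay beta")
  r <- .Call(C_gpc_scan_short, kind_code(kind), t, params$a, params$b,
             params$alpha, params$beta_h, policy)
  list(n_terms = as.integer(r$n_terms),
       max_term_log10 = as.integer(r$max_term_log10))
}

new_eval_result <- function(r, kind, t) {
  structure(
    list(value = hpnum(r$value), branch = r$branch,
         n_terms = as.integer(r$n_terms),
         max_term_log10 = if (is.na(r$max_term_log10)) NA_integer_
                          else as.integer(r$max_term_log10),
         working_digits = as.integer(r$working_digits),
         kind = kind, t = t),
    class = "gpc_eval")
}

#' @export
print.gpc_eval <- function(x, ...) {
  cat(sprintf("<gpc_eval> %s(t = %g h), %s branch, %d term(s), working %d digits%s\n",
              x$kind, x$t, x$branch, x$n_terms, x$working_digits,
              if (!is.na(x$max_term_log10))
                sprintf(", max |term| ~ 1e%d", x$max_term_log10) else ""))
  print(x$value)
  invisible(x)
}

#' @export
as.double.gpc_eval <- function(x, ...) as.numeric(x$value)

#' Evaluate a GPC function with a forced series branch
#'
#' \code{evaluate_short()} sums the primary (short-time) series using the
#' two-pass precision scheme: a machine-precision scan finds the largest
#' term magnitude, then every term is recomputed and summed at
#' \code{max_term_log10 + target_digits} working digits.
#' \code{evaluate_long()} uses the rearranged long-time algorithm:
#' closed-form gamma and asymptote parts plus a sum whose confluent
#' hypergeometric factors terminate under the Kummer transformation, with
#' monotonically decaying terms.  Both are valid for any \eqn{t>\beta};
#' they differ only in cost.  Use [gpc_evaluate()] for the automatic
#' \eqn{4\beta} dispatch.
#'
#' @inheritParams scan_short_terms
#' @return A \code{"gpc_eval"} object: \code{value} ([hpnum]),
#'   \code{branch}, \code{n_terms}, \code{max_term_log10},
#'   \code{working_digits}.
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' evaluate_short("pdf", 0.02, dog1, gpc_policy(30))
#' @export
evaluate_short <- function(kind, t, params, policy = gpc_policy()) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  r <- .Call(C_gpc_eval, kind_code(kind), t, params$a, params$b,
             params$alpha, params$beta_h, policy, 1L)
  new_eval_result(r, kind, t)
}

#' @rdname evaluate_short
#' @export
evaluate_long <- function(kind, t, params, policy = gpc_policy()) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  r <- .Call(C_gpc_eval, kind_code(kind), t, params$a, params$b,
             params$alpha, params$beta_h, policy, 2L)
  new_eval_result(r, kind, t)
}

#' Long-time asymptote of the GPC density
#'
#' The closed-form asymptote term
#' \eqn{-\pi\csc(\pi\alpha)\frac{b^a\beta^\alpha}{\Gamma(\alpha)}
#' t^{a-\alpha-1}\,{}_1\tilde F_1(a, a-\alpha; -bt)} alone, which the full
#' density approaches as \eqn{t \to \infty}.
#'
#' @inheritParams scan_short_terms
#' @return An [hpnum] scalar (1/h).
#' @export
asymptote_pdf <- function(t, params, policy = gpc_policy()) {
  stopifnot(inherits(params, "gpc_params"))
  policy <- as_policy(policy)
  t <- as.numeric(t)[1]
  if (t <= params$beta_h) stop("t must exceed the delay beta")
  hpnum(.Call(C_gpc_asym_pdf, t, params$a, params$b, params$alpha,
              params$beta_h, policy))
}

#' Ratio of consecutive simplified long-time terms
#'
#' \eqn{|T_{k+1}/T_k|} of the simplified long-time density summand, which
#' the convergence analysis bounds by approximately \eqn{\beta/(kt)} --
#' the basis for both the monotone-decay stopping rule and the
#' \eqn{t = 4\beta} branch point (worst next-term ratio about 1/4).
#'
#' @param k term index, >= 1.
#' @inheritParams scan_short_terms
#' @return A double.
#' @export
long_term_ratio <- function(k, t, params) {
  stopifnot(inherits(params, "gpc_params"))
  k <- as.numeric(k)[1]
  if (!is.finite(k) || k < 1 || k != floor(k)) stop("k must be an integer >= 1")
  t <- as.numeric(t)[1]
  if (t <= params$beta_h) stop("t must exceed the delay beta")
  .Call(C_long_term_ratio, k, t, params$a, params$b, params$alpha,
        params$beta_h)
}
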