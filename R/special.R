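#' Incomplete beta function with negative second parameter
#'
#' Computes \eqn{B_z(A,B) = \int_0^z u^{A-1}(1-u)^{B-1}\,du} at the
#' policy's precision.  \code{B} may be negative (non-integer): the
#' integral is then defined by the same convergent power series
#' \eqn{B_z(A,B) = z^A \sum_k (1-B)_k z^k / (k!\,(A+k))}.  For \eqn{z}
#' close to 1 the reflection identity
#' \eqn{B_z(A,B) = B(A,B) - B_{1-z}(B,A)} is used; these are exactly the
#' two evaluation routes the GPC series engines need, and
#' \code{beta_inc_reflect()} exposes the reflected route directly for
#' cross-checking.
#'
#' @param z upper integration limit in \eqn{[0,1]}.
#' @param A first parameter, > 0 (or any non-nonpositive-integer real for
#'   the internal series).
#' @param B second parameter; when \eqn{\le 0} it must not be within
#'   tolerance of a nonpositive integer.
#' @param policy a [gpc_policy] (or a digit count).
#' @param route \code{"auto"} (series for \eqn{z \le 0.75}, reflection
#'   otherwise), \code{"series"}, or \code{"reflect"}.
#' @return An [hpnum] scalar.
#' @examples
#' beta_inc(0.3, 2.5, -0.7, gpc_policy(30))
#' beta_inc(0.5, 1, 1, gpc_policy(20))   # uniform CDF: 0.5
#' @export
beta_inc <- function(z, A, B, policy = gpc_policy(), route = "auto") {
  policy <- as_policy(policy)
  z <- as.numeric(z)[1]
  if (!is.finite(z) || z < 0 || z > 1) stop("z must lie in [0, 1]")
  route <- match.arg(route, c("auto", "series", "reflect"))
  hpnum(.Call(C_beta_inc, z, as.numeric(A), as.numeric(B), policy,
              c(auto = 0L, series = 1L, reflect = 2L)[[route]]))
}

## note: z = 1 returns 0 immediately (B_0 = 0); z = 0 gives the complete beta

#' @rdname beta_inc
#' @details \code{beta_inc_reflect(z, A, B)} returns \eqn{B_{1-z}(A,B)}
#'   computed through the reflection identity, so that
#'   \code{beta_inc_reflect(1 - z, A, B)} must agree with
#'   \code{beta_inc(z, A, B)}.
#' @export
beta_inc_reflect <- function(z, A, B, policy = gpc_policy()) {
  policy <- as_policy(policy)
  z <- as.numeric(z)[1]
  if (!is.finite(z) || z < 0 || z > 1) stop("z must lie in [0, 1]")
  ## B_{1-z}(A,B) = B(A,B) - B_z(B,A), evaluated in one pass at working
  ## precision (the C route-2 path applied at argument 1-z)
  hpnum(.Call(C_beta_inc, 1 - z, as.numeric(A), as.numeric(B), policy, 2L))
}

#' Integration-by-parts reduction of the incomplete beta
#'
#' Returns \eqn{B_z(A+1,B)} through the identity
#' \eqn{B_z(A+1,B) = \frac{A}{A+B} B_z(A,B) - \frac{z^A (1-z)^B}{A+B}},
#' which relates consecutive rows of the GPC series and serves as an
#' independent self-test route.
#'
#' @inheritParams beta_inc
#' @return An [hpnum] scalar, \eqn{B_z(A+1,B)}.
#' @export
beta_ibp_reduce <- function(z, A, B, policy = gpc_policy()) {
  policy <- as_policy(policy)
  z <- as.numeric(z)[1]
  if (!is.finite(z) || z < 0 || z > 1) stop("z must lie in [0, 1]")
  if (abs(as.numeric(A) + as.numeric(B)) < 1e-12)
    stop("A + B is (near) zero: identity undefined")
  hpnum(.Call(C_beta_ibp, z, as.numeric(A), as.numeric(B), policy))
}

#' Kummer confluent hypergeometric function
#'
#' \eqn{{}_1F_1(A,B;x)} and its regularised form
#' \eqn{{}_1\tilde F_1 = {}_1F_1/\Gamma(B)} (entire in \eqn{B}).  For
#' large negative \eqn{x} the direct series suffers catastrophic
#' cancellation; the implementation therefore always applies the Kummer
#' transformation \eqn{{}_1F_1(A,B;x) = e^x {}_1F_1(B-A,B;-x)}, which for
#' the GPC long-time terms (\eqn{B - A = -k}) terminates after \eqn{k+1}
#' polynomial terms and otherwise yields a single-signed-tail series.
#' \code{method = "direct"} forces brute-force summation of the defining
#' series at precision elevated by \eqn{|x|\log_{10}e} digits, the oracle
#' route used in the tests.
#'
#' @param A,B,x real arguments; plain \code{hyp1f1} requires \code{B} not
#'   a nonpositive integer.
#' @param policy a [gpc_policy] (or a digit count).
#' @param method \code{"auto"} or \code{"direct"}.
#' @return An [hpnum] scalar.
#' @examples
#' hyp1f1(0.5, 0.5, 1, gpc_policy(30))       # = e
#' hyp1f1_reg(0.3, 2, 0, gpc_policy(20))     # = 1/Gamma(2) = 1
#' @export
hyp1f1 <- function(A, B, x, policy = gpc_policy(), method = "auto") {
  policy <- as_policy(policy)
  method <- match.arg(method, c("auto", "direct"))
  B <- as.numeric(B)
  if (B < 0.5 && abs(B - round(B)) < 1e-12)
    stop("1F1 pole: B is a nonpositive integer (use hyp1f1_reg)")
  hpnum(.Call(C_hyp1f1, as.numeric(A), B, as.numeric(x), policy, 0L,
              if (method == "direct") 1L else 0L))
}

#' @rdname hyp1f1
#' @export
hyp1f1_reg <- function(A, B, x, policy = gpc_policy(), method = "auto") {
  policy <- as_policy(policy)
  method <- match.arg(method, c("auto", "direct"))
  hpnum(.Call(C_hyp1f1, as.numeric(A), as.numeric(B), as.numeric(x), policy,
              1L, if (method == "direct") 1L else 0L))
}

#' Regularised upper incomplete gamma function
#'
#' \eqn{Q(a,x) = \Gamma(a,x)/\Gamma(a)}, the survival function of the
#' gamma distribution, evaluated by the power series (small \eqn{x}) or a
#' modified Lentz continued fraction (large \eqn{x}) at the policy's
#' precision.
#'
#' @param a shape, > 0.
#' @param x nonnegative argument.
#' @inheritParams beta_inc
#' @return An [hpnum] scalar in \eqn{[0,1]}.
#' @examples
#' gamma_reg_Q(1, 2, gpc_policy(25))   # = exp(-2)
#' @export
gamma_reg_Q <- function(a, x, policy = gpc_policy()) {
  policy <- as_policy(policy)
  a <- as.numeric(a)[1]; x <- as.numeric(x)[1]
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(x) || x < 0) stop("x must be >= 0")
  hpnum(.Call(C_gamma_regQ, a, x, policy))
}

#' Pochhammer symbol (rising factorial)
#'
#' \eqn{(x)_0 = 1}, \eqn{(x)_k = x (x+1) \cdots (x+k-1)}.
#'
#' @param x real base.
#' @param k nonnegative integer.
#' @param digits significant digits of the result.
#' @return An [hpnum] scalar.
#' @export
pochhammer <- function(x, k, digits = 40) {
  k <- as.numeric(k)[1]
  if (!is.finite(k) || k < 0 || k != floor(k)) stop("k must be a nonnegative integer")
  hpnum(.Call(C_pochhammer, as.numeric(x), k, as.numeric(digits)))
}
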