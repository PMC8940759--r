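#' GPC parameter set
#'
#' The four-parameter gamma-Pareto type I convolution: gamma shape \code{a}
#' (dimensionless) and rate \code{b} (1/h), Pareto shape \code{alpha}
#' (dimensionless, must not be an integer because the long-time algorithm
#' carries a \eqn{\csc(\pi\alpha)} factor) and Pareto delay/scale
#' \eqn{\beta} (the circulation delay).  Internally time is in hours;
#' \code{beta} may be given in seconds (\code{beta_s}, as printed in
#' study tables) or hours (\code{beta_h}).
#'
#' @param a gamma shape, > 0.
#' @param b gamma rate in 1/h, > 0.
#' @param alpha Pareto shape, > 0 and farther than 1e-8 from any integer.
#' @param beta_s Pareto delay in seconds (converted to hours), or
#' @param beta_h Pareto delay in hours (give exactly one of the two).
#'
#' @return Object of class \code{"gpc_params"} with fields \code{a},
#'   \code{b}, \code{alpha}, \code{beta_h}.
#' @examples
#' # metformin disposition in dog 1 (table-rounded values)
#' gpc_params(a = 0.3493, b = 0.7318, alpha = 0.2644, beta_s = 25)
#' @export
gpc_params <- function(a, b, alpha, beta_s = NULL, beta_h = NULL) {
  if (is.null(beta_h) == is.null(beta_s))
    stop("give exactly one of beta_s (seconds) or beta_h (hours)")
  if (is.null(beta_h)) beta_h <- as.numeric(beta_s) / 3600
  a <- as.numeric(a); b <- as.numeric(b); alpha <- as.numeric(alpha)
  beta_h <- as.numeric(beta_h)
  stopifnot(length(a) == 1, length(b) == 1, length(alpha) == 1,
            length(beta_h) == 1)
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(b) || b <= 0) stop("b must be > 0")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(beta_h) || beta_h <= 0) stop("beta must be > 0")
  if (abs(alpha - round(alpha)) <= 1e-8)
    stop("alpha must not be within 1e-8 of an integer (csc(pi*alpha) pole)")
  structure(list(a = a, b = b, alpha = alpha, beta_h = beta_h),
            class = "gpc_params")
}

#' @export
print.gpc_params <- function(x, ...) {
  cat(sprintf(
    "<gpc_params> a = %g, b = %g /h, alpha = %g, beta = %g s (%g h)\n",
    x$a, x$b, x$alpha, x$beta_h * 3600, x$beta_h))
  invisible(x)
}

#' AUC-scaled concentration model
#'
#' A serum concentration curve \eqn{C(t) = AUC \cdot f(t)} where \eqn{f}
#' is the GPC density.  When the administered dose is given, clearance
#' follows as \eqn{CL = dose/AUC}.
#'
#' @param params a [gpc_params] object.
#' @param auc area under the concentration curve, mg h/L, > 0.
#' @param dose optional dose in mg/kg; enables the \code{cl} field,
#'   L/(h kg).
#' @return Object of class \code{"gpc_model"}.
#' @examples
#' par1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' mod <- gpc_model(par1, auc = 31.16, dose = 18.248)
#' mod$cl * 1000 / 60   # clearance in mL/(min kg)
#' @export
gpc_model <- function(params, auc, dose = NULL) {
  stopifnot(inherits(params, "gpc_params"))
  auc <- as.numeric(auc)[1]
  if (!is.finite(auc) || auc <= 0) stop("auc must be > 0")
  cl <- NULL
  if (!is.null(dose)) {
    dose <- as.numeric(dose)[1]
    if (!is.finite(dose) || dose <= 0) stop("dose must be > 0")
    cl <- dose / auc
  }
  structure(list(params = params, auc = auc, dose = dose, cl = cl),
            class = "gpc_model")
}

#' @export
print.gpc_model <- function(x, ...) {
  cat(sprintf("<gpc_model> AUC = %g mg*h/L%s\n", x$auc,
              if (!is.null(x$dose))
                sprintf(", dose = %g mg/kg, CL = %g L/(h*kg) [%.3g mL/(min*kg)]",
                        x$dose, x$cl, x$cl * 1000 / 60) else ""))
  print(x$params)
  invisible(x)
}

#' Repeated intravenous bolus dosing regimen
#'
#' Equal doses at a fixed interval; dose times are
#' \eqn{0, \tau, \ldots, (n-1)\tau}.
#'
#' @param interval_h dosing interval \eqn{\tau} in hours, > 0.
#' @param n_doses number of doses, >= 1.
#' @param dose_mg_per_kg dose size (per dose), mg/kg; optional, only used
#'   when a regimen is combined with a model that lacks its own dose.
#' @return Object of class \code{"dose_regimen"} with derived
#'   \code{dose_times}.
#' @examples
#' dose_regimen(interval_h = 24, n_doses = 14)
#' @export
dose_regimen <- function(interval_h, n_doses, dose_mg_per_kg = NULL) {
  interval_h <- as.numeric(interval_h)[1]
  n_doses <- as.integer(n_doses)[1]
  if (!is.finite(interval_h) || interval_h <= 0)
    stop("interval_h must be > 0")
  if (is.na(n_doses) || n_doses < 1) stop("n_doses must be >= 1")
  structure(list(interval_h = interval_h, n_doses = n_doses,
                 dose_times = interval_h * (seq_len(n_doses) - 1),
                 dose_mg_per_kg = dose_mg_per_kg),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %d dose(s) every %g h%s\n", x$n_doses,
              x$interval_h,
              if (!is.null(x$dose_mg_per_kg))
                sprintf(", %g mg/kg each", x$dose_mg_per_kg) else ""))
  invisible(x)
}

kind_code <- function(kind) {
  kind <- match.arg(kind, c("pdf", "cdf", "supercdf", "deriv"))
  c(pdf = 0L, cdf = 1L, supercdf = 2L, deriv = 3L)[[kind]]
}
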