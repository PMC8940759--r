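#' Concentration-time series
#'
#' A single subject's observed (or simulated) concentrations: strictly
#' increasing positive times in hours and strictly positive
#' concentrations in mg/L (positivity is required by the relative loss).
#'
#' @param times hours, strictly increasing, > 0.
#' @param concs mg/L, > 0, same length.
#' @param subject_id label.
#' @return Object of class \code{"conc_series"} (also a data.frame-like
#'   list).
#' @export
conc_series <- function(times, concs, subject_id = "subject") {
  times <- as.numeric(times); concs <- as.numeric(concs)
  if (length(times) != length(concs)) stop("times and concs lengths differ")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be > 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(concs)) || any(concs <= 0))
    stop("concs must be > 0 (required by the relative loss)")
  structure(list(times = times, concs = concs, subject_id = subject_id),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> '%s': %d samples, %.3g to %.3g h\n",
              x$subject_id, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read/write concentration CSV (columns time_h, conc_mg_L)
#'
#' @param path file path.
#' @param data a [conc_series].
#' @return \code{read_concentration_csv} returns a [conc_series].
#' @export
read_concentration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "conc_mg_L") %in% names(d)))
    stop("CSV must have columns time_h and conc_mg_L")
  conc_series(d$time_h, d$conc_mg_L,
              subject_id = if ("subject_id" %in% names(d))
                as.character(d$subject_id[1]) else "subject")
}

#' @rdname read_concentration_csv
#' @export
write_concentration_csv <- function(data, path) {
  stopifnot(inherits(data, "conc_series"))
  utils::write.csv(
    data.frame(time_h = sprintf("%.17g", data$times),
               conc_mg_L = sprintf("%.17g", data$concs)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## model predictions at the data times
predict_conc <- function(theta, times, eval = "fast", digits = 25) {
  params <- gpc_params(theta[["a"]], theta[["b"]], theta[["alpha"]],
                       beta_s = theta[["beta_s"]])
  if (eval == "fast") {
    theta[["auc"]] * dgpc(times, params)
  } else {
    pol <- gpc_policy(digits)
    theta[["auc"]] * vapply(times, function(tt)
      as.numeric(gpc_evaluate("pdf", tt, params, pol)), 0.0)
  }
}

#' Relative root-mean-square (proportional) loss
#'
#' The 1/C^2-weighted least-squares criterion
#' \eqn{\mathrm{rrms} = \sqrt{\frac1n \sum_i
#'   \left(\frac{\hat C_i - C_i}{C_i}\right)^2}},
#' matching a measurement system with proportional error.
#'
#' @param model a [gpc_model] (or a named parameter vector as used
#'   internally).
#' @param data a [conc_series].
#' @return The rrms as a fraction (0.086 = 8.6\%).
#' @examples
#' dog1 <- gpc_params(0.3493, 0.7318, 0.2644, beta_s = 25)
#' mod <- gpc_model(dog1, auc = 31.16)
#' d <- conc_series(c(1, 2, 4), 1.1 * mod$auc * dgpc(c(1, 2, 4), dog1))
#' rrms_loss(mod, d)   # exactly 0.10
#' @export
rrms_loss <- function(model, data) {
  stopifnot(inherits(data, "conc_series"))
  pred <- if (inherits(model, "gpc_model")) {
    model$auc * dgpc(data$times, model$params)
  } else {
    predict_conc(model, data$times)
  }
  sqrt(mean(((pred - data$concs) / data$concs)^2))
}

## weighted R^2 consistent with 1/C^2 weights
rsq_weighted <- function(obs, pred) {
  wmean <- sum(1 / obs) / sum(1 / obs^2)
  1 - sum(((obs - pred) / obs)^2) / sum(((obs - wmean) / obs)^2)
}

#' Default parameter bounds for fitting
#'
#' Dog-study parameter ranges widened by 50\% (the delay beta is kept in
#' the assay-constrained 25-30 s window).
#' @return Named list of \code{c(lower, upper)} pairs for \code{a},
#'   \code{b}, \code{alpha}, \code{beta_s}, \code{auc}.
#' @export
default_fit_bounds <- function() {
  list(a = c(0.17, 1.22), b = c(0.30, 1.66), alpha = c(0.06, 0.40),
       beta_s = c(25, 30), auc = c(6, 47))
}

#' Fit the AUC-scaled GPC model by multi-start Nelder-Mead
#'
#' Minimises [rrms_loss()] over \eqn{(a, b, \alpha, \beta, AUC)} with a
#' quadratic penalty outside the box bounds, restarting Nelder-Mead from
#' \code{n_starts} seeded points inside the bounds and keeping the best
#' minimum.  No gradient post-processing is applied (the loss surface is
#' nonconvex and interior-point refinement fails on it).  The objective
#' evaluates the model on the fast double path by default
#' (\code{eval = "fast"}); \code{eval = "hp"} sums the series at
#' \code{eval_digits} significant digits instead.  Either way the final
#' parameters are re-evaluated at \code{policy} precision for the
#' reported loss and \eqn{R^2}.
#'
#' @param data a [conc_series].
#' @param dose dose in mg/kg; enables clearance \code{cl = dose/auc}.
#' @param bounds named list as [default_fit_bounds()].
#' @param policy a [gpc_policy] for the final re-evaluation.
#' @param seed integer seed making the multi-start deterministic.
#' @param n_starts number of Nelder-Mead starts.
#' @param init optional named start vector (appended to the seeded
#'   starts).
#' @param eval \code{"fast"} (double-precision objective) or \code{"hp"}.
#' @param eval_digits working digits of the \code{"hp"} objective.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return Object of class \code{"gpc_fit"}: \code{params}
#'   ([gpc_params]), \code{auc}, \code{cl}, \code{rrms}, \code{r2},
#'   \code{theta}, \code{n_evals}, \code{converged}, \code{seed}.
#' @export
fit_gpc <- function(data, dose = NULL, bounds = default_fit_bounds(),
                    policy = gpc_policy(30), seed = 1, n_starts = 5L,
                    init = NULL, eval = c("fast", "hp"), eval_digits = 25,
                    maxit = 600) {
  stopifnot(inherits(data, "conc_series"))
  eval <- match.arg(eval)
  policy <- as_policy(policy)
  lower <- vapply(bounds, `[`, 0.0, 1)
  upper <- vapply(bounds, `[`, 0.0, 2)
  pnames <- names(bounds)
  scale <- upper - lower

  clamp <- function(th) pmin(pmax(th, lower), upper)
  objective <- function(th) {
    names(th) <- pnames
    pen <- sum(pmax(0, (lower - th) / scale, (th - upper) / scale)^2) * 100
    thc <- clamp(th)
    ## keep alpha clear of the integer pole
    if (abs(thc[["alpha"]] - round(thc[["alpha"]])) <= 1e-8)
      thc[["alpha"]] <- round(thc[["alpha"]]) + 1e-6
    pred <- predict_conc(thc, data$times, eval, eval_digits)
    if (any(!is.finite(pred)) || all(pred <= 0)) return(1e6 + pen)
    sqrt(mean(((pred - data$concs) / data$concs)^2)) + pen
  }

  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i)
    lower + stats::runif(length(lower)) * scale)
  if (!is.null(init)) starts <- c(list(init[pnames]), starts)
  if (!length(starts))
    stop("no starting points: give n_starts > 0 or an init vector")

  best <- NULL
  n_evals <- 0L
  any_conv <- FALSE
  for (st in starts) {
    o <- stats::optim(unlist(st), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12,
                                     parscale = scale))
    n_evals <- n_evals + o$counts[["function"]]
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## one chained restart from the incumbent: a fresh simplex around the
  ## best point digs Nelder-Mead out of collapsed-simplex stalls
  o <- stats::optim(best$par, objective, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-12,
                                   parscale = scale))
  n_evals <- n_evals + o$counts[["function"]]
  if (o$value < best$value) best <- o
  theta <- clamp(best$par)
  names(theta) <- pnames
  params <- gpc_params(theta[["a"]], theta[["b"]], theta[["alpha"]],
                       beta_s = theta[["beta_s"]])
  ## final re-evaluation at full policy precision
  pred <- theta[["auc"]] * vapply(data$times, function(tt)
    as.numeric(gpc_evaluate("pdf", tt, params, policy)), 0.0)
  rrms <- sqrt(mean(((pred - data$concs) / data$concs)^2))
  structure(list(
    params = params, auc = theta[["auc"]],
    cl = if (!is.null(dose)) dose / theta[["auc"]] else NULL,
    dose = dose, rrms = rrms, r2 = rsq_weighted(data$concs, pred),
    theta = theta, n_evals = n_evals, converged = any_conv,
    seed = seed, data = data, policy = policy
  ), class = "gpc_fit")
}

#' @export
print.gpc_fit <- function(x, ...) {
  cat(sprintf(
    "<gpc_fit> a=%.4g b=%.4g alpha=%.4g beta=%.4g s AUC=%.4g; rrms %.3g%%, R2 %.5f%s\n",
    x$theta[["a"]], x$theta[["b"]], x$theta[["alpha"]], x$theta[["beta_s"]],
    x$auc, 100 * x$rrms, x$r2,
    if (!is.null(x$cl)) sprintf(", CL %.3g mL/(min*kg)", x$cl * 1000 / 60)
    else ""))
  invisible(x)
}
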