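#' Arbitrary-precision evaluation policy
#'
#' Controls the precision of every series evaluation: the number of
#' significant decimal digits carried in results, the guard digits added to
#' the working precision, the absolute stopping threshold for the outer
#' sums (stop once the magnitude of the current term, past the magnitude
#' peak, falls below \code{10^stop_exponent}), and a hard cap on the number
#' of summed terms so that pathological inputs fail loudly instead of
#' spinning.
#'
#' @param target_digits significant decimal digits of the result
#'   (default 65, minimum 15).
#' @param guard_digits extra working digits (default 10).
#' @param stop_exponent stop the outer sums when the current term magnitude
#'   is below \code{10^stop_exponent}; defaults to \code{-target_digits}.
#' @param max_terms cap on summed terms (default \code{1e6}).
#'
#' @return An object of class \code{"gpc_policy"}.
#' @examples
#' gpc_policy()                 # the 65-digit default
#' gpc_policy(target_digits = 30)
#' @export
gpc_policy <- function(target_digits = 65, guard_digits = 10,
                       stop_exponent = -target_digits, max_terms = 1e6) {
  target_digits <- as.numeric(target_digits)[1]
  guard_digits <- as.numeric(guard_digits)[1]
  stop_exponent <- as.numeric(stop_exponent)[1]
  max_terms <- as.numeric(max_terms)[1]
  if (!is.finite(target_digits) || target_digits < 15)
    stop("target_digits must be >= 15")
  if (!is.finite(guard_digits) || guard_digits < 0)
    stop("guard_digits must be >= 0")
  if (!is.finite(max_terms) || max_terms < 1)
    stop("max_terms must be >= 1")
  if (!is.finite(stop_exponent))
    stop("stop_exponent must be finite")
  structure(
    list(target_digits = target_digits, guard_digits = guard_digits,
         stop_exponent = stop_exponent, max_terms = max_terms),
    class = "gpc_policy")
}

as_policy <- function(policy) {
  if (inherits(policy, "gpc_policy")) return(policy)
  if (is.numeric(policy) && length(policy) == 1) return(gpc_policy(policy))
  stop("'policy' must be a gpc_policy object or a digit count")
}

#' @export
print.gpc_policy <- function(x, ...) {
  cat(sprintf(
    "<gpc_policy> %d significant digits (+%d guard), stop |term| < 1e%d, cap %g terms\n",
    as.integer(x$target_digits), as.integer(x$guard_digits),
    as.integer(x$stop_exponent), x$max_terms))
  invisible(x)
}
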