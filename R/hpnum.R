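#' High-precision numbers as decimal strings
#'
#' Results of the arbitrary-precision routines are carried as decimal
#' strings (class \code{"hpnum"}) because 65-digit values do not fit in a
#' double.  \code{hpnum()} tags a character vector (or coerces numerics),
#' \code{as.numeric()} converts with the usual double rounding, and
#' \code{hp_digits_agree()} counts the number of matching leading
#' significant digits between two values, the comparison currency used
#' throughout the package's tests.
#'
#' @param x character vector of decimal numbers (any format
#'   \code{mpfr_strtofr} accepts), or a numeric vector.
#' @return \code{hpnum()} returns an object of class \code{"hpnum"}.
#' @examples
#' x <- hpnum("3.14159265358979323846264338327950288")
#' as.numeric(x)
#' hp_digits_agree(x, hpnum(pi))   # double pi carries ~16 digits
#' @export
hpnum <- function(x) {
  # 35 digits renders the exact binary value of a double well past its
  # 17-digit round-trip precision
  if (is.numeric(x)) x <- sprintf("%.35g", x)
  if (inherits(x, "hpnum")) return(x)
  stopifnot(is.character(x))
  structure(x, class = "hpnum")
}

#' @export
print.hpnum <- function(x, ...) {
  cat(format(unclass(x)), sep = "\n")
  invisible(x)
}

#' @export
as.double.hpnum <- function(x, ...) as.numeric(unclass(x))

#' @rdname hpnum
#' @param y second value (recycled against \code{x}).
#' @return \code{hp_digits_agree()} returns a numeric vector: matching
#'   leading significant digits, \code{Inf} when the parsed values are
#'   identical, 0 when either is zero while the other is not.
#' @export
hp_digits_agree <- function(x, y) {
  x <- unclass(hpnum(x)); y <- unclass(hpnum(y))
  n <- max(length(x), length(y))
  .Call(C_hp_digits_agree, rep_len(x, n), rep_len(y, n))
}

#' @rdname hpnum
#' @details \code{hp_places_agree()} counts matching decimal places
#'   (\code{floor(-log10 |x - y|)}), the natural agreement measure under an
#'   absolute series-stopping rule; \code{hp_digits_agree()} counts leading
#'   significant digits (relative agreement).
#' @param digits working digits for the internal subtraction.
#' @export
hp_places_agree <- function(x, y, digits = 80) {
  d <- abs(as.numeric(hp_sub(x, y, digits)))
  ifelse(d == 0, Inf, floor(-log10(d)))
}

hp_op <- function(op, x, y, digits = 40) {
  hpnum(.Call(C_hp_arith, as.integer(op), unclass(hpnum(x)),
              unclass(hpnum(y)), as.numeric(digits)))
}

#' Elementary arithmetic on high-precision decimal strings
#'
#' @param x,y values coercible with [hpnum()].
#' @param digits working/result significant digits.
#' @return An [hpnum] vector.
#' @export
hp_add <- function(x, y, digits = 40) hp_op(1L, x, y, digits)
#' @rdname hp_add
#' @export
hp_sub <- function(x, y, digits = 40) hp_op(2L, x, y, digits)
#' @rdname hp_add
#' @export
hp_mul <- function(x, y, digits = 40) hp_op(3L, x, y, digits)
#' @rdname hp_add
#' @export
hp_div <- function(x, y, digits = 40) hp_op(4L, x, y, digits)

#' @rdname hp_add
#' @export
hp_sum <- function(x, digits = 40) {
  hpnum(.Call(C_hp_sum, unclass(hpnum(x)), as.numeric(digits)))
}
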