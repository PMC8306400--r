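#' @keywords internal
"_PACKAGE"

# Cumulative trapezoidal integral of y over x (x ascending). Returns a vector
# the same length as x with F[1] = 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

# Definite trapezoidal integral of y over [a, b], linearly interpolating the
# cumulative integral at the interval ends. x must be ascending and cover
# [a, b].
trapz_between <- function(x, y, a, b) {
  Fc <- cumtrapz(x, y)
  f <- stats::approxfun(x, Fc, rule = 2)
  f(b) - f(a)
}

# Average ranks (ties get the mean of the spanned ranks).
avg_rank <- function(x) rank(x, ties.method = "average")

# Tie term sum over groups of tied values: sum(t^3 - t).
tie_term <- function(x) {
  tt <- table(x)
  sum(tt^3 - tt)
}

kelvin <- function(celsius) celsius + 273.15

#' Gas constant
#'
#' Universal gas constant in J/(mol K), used for Arrhenius activation
#' energies.
#' @export
GAS_CONSTANT <- 8.314

`%||%` <- function(a, b) if (is.null(a)) b else a
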