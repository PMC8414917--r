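#' Linear-in-time rate functions
#'
#' Root elongation and leaf-area expansion are represented as rates that are
#' linear in plant age, the first derivative of a quadratic growth curve.
#' Evaluation is clamped at zero so a declining fitted parabola can never
#' produce negative elongation.
#'
#' @param slope change in rate per day (e.g. cm d^-2).
#' @param intercept rate at day 0 (e.g. cm d^-1).
#' @return An object of class `rate_function`.
#' @export
rate_function <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(kind = "linear", slope = slope, intercept = intercept),
            class = "rate_function")
}

#' Evaluate a rate function at time `t`
#'
#' @param rate a [rate_function()].
#' @param t days after planting (vectorized).
#' @return Non-negative rate(s) at `t`.
#' @export
eval_rate <- function(rate, t) {
  stopifnot(inherits(rate, "rate_function"))
  pmax(0, rate$slope * t + rate$intercept)
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("<rate_function> max(0, %g * t + %g)\n", x$slope, x$intercept))
  invisible(x)
}

#' Derive a growth-rate function from serial harvest measurements
#'
#' Fits a least-squares quadratic `a t^2 + b t + c` to size measurements taken
#' at several harvest days and returns its first derivative `2 a t + b` as a
#' [rate_function()]. This is how axial elongation rates and the leaf-area
#' expansion rate are derived from destructive-harvest series.
#'
#' @param times harvest days (>= 3 distinct values).
#' @param measurements sizes at `times` (cm or cm^2), non-negative.
#' @return A [rate_function()] with slope `2a` and intercept `b`.
#' @export
fit_growth_rate <- function(times, measurements) {
  if (length(times) != length(measurements))
    stop("times and measurements must have equal length")
  if (length(unique(times)) < 3L)
    stop("degenerate fit: need at least 3 distinct time points")
  if (any(measurements < 0)) stop("measurements must be non-negative")
  fit <- stats::lm(measurements ~ times + I(times^2))
  cf <- stats::coef(fit)
  b <- unname(cf[["times"]])
  a <- unname(cf[["I(times^2)"]])
  rate_function(slope = 2 * a, intercept = b)
}

#' Draw a branching frequency from its uniform range
#'
#' Lateral branching frequencies are heritable but variable; each branching
#' event draws a frequency uniformly from the class range. Reproducible under
#' the session RNG (seed it with [set.seed()]).
#'
#' @param range numeric pair `(low, high)`, branches cm^-1.
#' @param n number of draws.
#' @return `n` draws, uniform on `[low, high]`.
#' @export
sample_branching_frequency <- function(range, n = 1L) {
  if (length(range) != 2L || any(!is.finite(range)))
    stop("range must be a finite (low, high) pair")
  if (any(range < 0)) stop("branching frequencies must be non-negative")
  if (range[1] > range[2]) stop("range low must be <= high")
  if (range[1] == range[2]) return(rep(range[1], n))
  stats::runif(n, range[1], range[2])
}
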