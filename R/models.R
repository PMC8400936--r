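#' Urea concentration under first-order ureolysis
#'
#' Evaluates the integrated first-order rate law
#' `c_urea0 * exp(-k_urea * t * c_x)` at the given times. The curve is
#' strictly decreasing in `t` whenever `k_urea * c_x > 0` and constant at
#' `c_urea0` for a zero rate.
#'
#' @param t time in hours; nonnegative, vectorized.
#' @param params an [ureolysis_params()] object.
#' @return Urea concentration (g/L), same length as `t`.
#' @export
#' @examples
#' p <- ureolysis_params(k_urea = 0.04, c_urea0 = 19.99)
#' urea_model(c(0, 24, 72), p)
urea_model <- function(t, params) {
  stopifnot(inherits(params, "ureolysis_params"), is.numeric(t))
  if (any(t < 0)) stop("time 't' must be nonnegative", call. = FALSE)
  params$c_urea0 * exp(-params$k_urea * t * params$c_x)
}

#' Four-parameter sigmoid trajectory
#'
#' Evaluates `y(t) = d + (a - d) / (1 + (t/c)^b)`. At `t = 0` the term
#' `(0/c)^b` is defined as 0 for `b > 0`, so `y(0) = a` by continuity;
#' `y(c) = (a+d)/2` and `y(t) -> d` as `t` grows.
#'
#' @param t time (hours or days, matching the data); nonnegative, vectorized.
#' @param params a [sigmoid_params()] object.
#' @return Modeled value (pH, log cells, or g precipitate), same length as `t`.
#' @export
#' @examples
#' p <- sigmoid_params(a = 7.19, d = 9.15, c = 3.07, b = 1.37)
#' sigmoid_model(c(0, 3.07, 72), p)
sigmoid_model <- function(t, params) {
  stopifnot(inherits(params, "sigmoid_params"), is.numeric(t))
  if (any(t < 0)) stop("time 't' must be nonnegative", call. = FALSE)
  .sigmoid(t, params$a, params$d, params$c, params$b)
}

# raw evaluation used by both the exported model and the fitting residuals;
# (t/c)^b at t = 0 is forced to 0 so y(0) = a exactly
.sigmoid <- function(t, a, d, c, b) {
  ratio <- ifelse(t == 0, 0, (t / c)^b)
  d + (a - d) / (1 + ratio)
}

#' Free calcium concentration under first-order precipitation
#'
#' Evaluates `c_ca0 * exp(-k_precipitate * t)`, the integrated
#' non-affinity-based first-order rate law for Ca2+ removal from solution
#' (one mole of CaCO3 formed per mole of Ca2+ removed).
#'
#' @param t time in days; nonnegative, vectorized.
#' @param params a [precipitation_params()] object.
#' @return Free Ca2+ concentration (mg/L), same length as `t`.
#' @export
#' @examples
#' p <- precipitation_params(k_precipitate = 0.84, c_ca0 = 1282.34)
#' ca_model(0:3, p)
ca_model <- function(t, params) {
  stopifnot(inherits(params, "precipitation_params"), is.numeric(t))
  if (any(t < 0)) stop("time 't' must be nonnegative", call. = FALSE)
  params$c_ca0 * exp(-params$k_precipitate * t)
}

#' Percent reduction of free calcium at a given time
#'
#' Closed form `100 * (1 - exp(-k_precipitate * t))`: the fraction of the
#' initial free Ca2+ removed by time `t` under first-order kinetics,
#' independent of the initial concentration.
#'
#' @param params a [precipitation_params()] object (or a bare nonnegative
#'   rate coefficient).
#' @param t time in days; nonnegative, vectorized.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' percent_reduction(precipitation_params(4.84, 1266), t = 1)
percent_reduction <- function(params, t) {
  k <- if (inherits(params, "precipitation_params")) params$k_precipitate
       else params
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0, is.numeric(t))
  if (any(t < 0)) stop("time 't' must be nonnegative", call. = FALSE)
  100 * (1 - exp(-k * t))
}

#' Half-life of a first-order process
#'
#' @param k positive rate coefficient; the returned half-life is in the
#'   reciprocal unit of `k` (hours for ureolysis, days for precipitation).
#' @return `log(2) / k`.
#' @export
#' @examples
#' half_life(0.10) # ~6.93 h
half_life <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("'k' must be positive for a finite half-life", call. = FALSE)
  log(2) / k
}
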