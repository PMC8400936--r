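#' Parameter set for first-order ureolysis kinetics
#'
#' Urea depletion under a constant viable-cell density follows
#' \deqn{c_{Urea}(t) = c_{Urea}(0) \exp(-k_{Urea} \, t \, c_X)}
#' where `k_urea` is the first-order rate coefficient, `c_urea0` the initial
#' urea concentration and `c_x` the (assumed constant) viable-cell density.
#' Because `k_urea` and `c_x` enter only as a product, `c_x` defaults to a
#' normalized dimensionless 1 so that the fitted quantity is the effective
#' rate; supply a measured cell density to re-express the coefficient.
#'
#' @param k_urea first-order ureolysis rate coefficient (per hour per
#'   cell-density unit); must be >= 0.
#' @param c_urea0 initial urea concentration (g/L); must be > 0.
#' @param c_x constant viable-cell density (normalized unit, default 1);
#'   must be > 0.
#' @return An object of class `ureolysis_params`.
#' @seealso [urea_model()], [fit_ureolysis()]
#' @export
#' @examples
#' ureolysis_params(k_urea = 0.04, c_urea0 = 19.99)
ureolysis_params <- function(k_urea, c_urea0, c_x = 1) {
  stopifnot(is.numeric(k_urea), length(k_urea) == 1L, is.finite(k_urea),
            is.numeric(c_urea0), length(c_urea0) == 1L, is.finite(c_urea0),
            is.numeric(c_x), length(c_x) == 1L, is.finite(c_x))
  if (k_urea < 0) stop("'k_urea' must be nonnegative", call. = FALSE)
  if (c_urea0 <= 0) stop("'c_urea0' must be positive", call. = FALSE)
  if (c_x <= 0) stop("'c_x' must be positive", call. = FALSE)
  structure(list(k_urea = k_urea, c_urea0 = c_urea0, c_x = c_x),
            class = c("ureolysis_params", "kinetic_params"))
}

#' Parameter set for the four-parameter sigmoid
#'
#' The four-parameter logistic (Hill-type) trajectory
#' \deqn{y(t) = d + \frac{a - d}{1 + (t/c)^b}}
#' describes pH, log viable-cell counts and precipitate mass over time:
#' `a` is the value at t = 0, `d` the asymptote as t grows, `c` the
#' midpoint (inflection) time where y = (a+d)/2, and `b` the Hill slope
#' controlling steepness at `c`. Orientation (rising or falling) is carried
#' by the relative magnitudes of `a` and `d`, so `b` must be positive.
#'
#' @param a initial asymptote, in the units of the modeled variable.
#' @param d final asymptote, same units.
#' @param c midpoint time; must be > 0 (same unit as the time axis).
#' @param b Hill slope (dimensionless); must be > 0.
#' @return An object of class `sigmoid_params`.
#' @seealso [sigmoid_model()], [fit_sigmoid()]
#' @export
#' @examples
#' sigmoid_params(a = 7.19, d = 9.15, c = 3.07, b = 1.37)
sigmoid_params <- function(a, d, c, b) {
  vals <- c(a = a, d = d, c = c, b = b)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (c <= 0) stop("midpoint time 'c' must be positive", call. = FALSE)
  if (b <= 0) stop("Hill slope 'b' must be positive", call. = FALSE)
  structure(list(a = a, d = d, c = c, b = b),
            class = c("sigmoid_params", "kinetic_params"))
}

#' Parameter set for first-order calcium precipitation kinetics
#'
#' Free Ca2+ removal during MICP, proxied one-to-one to CaCO3 formation,
#' follows \deqn{c_{Ca}(t) = c_{Ca}(0) \exp(-k_{precipitate} \, t)}.
#'
#' @param k_precipitate first-order Ca2+ removal rate coefficient (per
#'   day); must be >= 0.
#' @param c_ca0 initial free-calcium concentration (mg/L); must be > 0.
#' @return An object of class `precipitation_params`.
#' @seealso [ca_model()], [fit_precipitation()], [percent_reduction()]
#' @export
#' @examples
#' precipitation_params(k_precipitate = 4.84, c_ca0 = 1266)
precipitation_params <- function(k_precipitate, c_ca0) {
  stopifnot(is.numeric(k_precipitate), length(k_precipitate) == 1L,
            is.finite(k_precipitate),
            is.numeric(c_ca0), length(c_ca0) == 1L, is.finite(c_ca0))
  if (k_precipitate < 0) stop("'k_precipitate' must be nonnegative", call. = FALSE)
  if (c_ca0 <= 0) stop("'c_ca0' must be positive", call. = FALSE)
  structure(list(k_precipitate = k_precipitate, c_ca0 = c_ca0),
            class = c("precipitation_params", "kinetic_params"))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<", class(x)[1L], "> ", sep = "")
  cat(paste(names(x), signif(unlist(x), 6), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
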