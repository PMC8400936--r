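#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Multistart bounded Levenberg-Marquardt over a residual function.
# `starts` is a matrix with one row per start; returns the best-deviance
# solution together with a truthful convergence flag.
.ms_fit <- function(starts, resid_fn, lower, upper) {
  best <- NULL
  total_iter <- 0L
  ctrl <- nls.lm.control(ftol = 1e-12, ptol = 1e-12, gtol = 0, maxiter = 1000)
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(starts[i, ], lower), upper)
    fit <- tryCatch(
      nls.lm(par = par0, fn = resid_fn, lower = lower, upper = upper,
             control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    total_iter <- total_iter + fit$niter
    ss <- fit$deviance
    if (is.null(best) || ss < best$ss) {
      best <- list(par = coef(fit), ss = ss,
                   converged = fit$info %in% 1:4, info = fit$info)
    }
  }
  if (is.null(best)) return(NULL)
  best$n_iter <- total_iter
  best
}

# Assemble the common fit-result container.
.fit_result <- function(model, params, n_par, traj, fitted, converged,
                        n_iter, message = NULL) {
  gof <- goodness_of_fit(traj$values, fitted)
  structure(list(model = model, strain = traj$strain, variable = traj$variable,
                 params = params, n_par = n_par,
                 r2 = gof$r2, rmse = gof$rmse, residuals = gof$residuals,
                 fitted = fitted, times = traj$times, observed = traj$values,
                 converged = converged, n_iter = n_iter,
                 lack_of_fit_p = NA_real_, message = message),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit:", x$model, "> ", x$strain, " / ", x$variable, "\n", sep = "")
  print(x$params)
  cat("  r2 = ", signif(x$r2, 4), ", rmse = ", signif(x$rmse, 4),
      ", converged = ", x$converged, "\n", sep = "")
  if (!is.null(x$message)) cat("  note: ", x$message, "\n", sep = "")
  invisible(x)
}

# Log-domain initialization for an exponential decay: regress log(value)
# on time over the strictly positive observations. Robust to steep decays
# where most samples sit near zero.
.exp_log_init <- function(times, values) {
  pos <- values > 0
  if (sum(pos) >= 2L && length(unique(times[pos])) >= 2L) {
    co <- stats::coef(stats::lm(log(values[pos]) ~ times[pos]))
    k0 <- max(0, -co[[2L]])
    c00 <- exp(co[[1L]])
  } else {
    k0 <- 0.1
    c00 <- max(values, 1e-6)
  }
  c(k = k0, c0 = c00)
}

.exp_starts <- function(times, values, n_starts) {
  init <- .exp_log_init(times, values)
  c00 <- max(init["c0"], max(values), 1e-6)
  kk <- unique(c(init[["k"]], 10^seq(-3, 1, length.out = max(1L, n_starts - 1L))))
  cbind(k = kk[seq_len(min(length(kk), n_starts))], c0 = c00)
}

# Shared engine for the two exponential-decay fits (ureolysis, calcium).
.fit_exponential <- function(traj, rate_scale = 1, fix_c0 = FALSE, starts = 8L,
                             make_params, model_name) {
  tt <- traj$times
  vv <- traj$values
  if (length(unique(tt)) < 3L)
    stop("need at least 3 distinct time points for an exponential fit",
         call. = FALSE)
  if (all(vv == 0)) {
    fit <- .fit_result(model_name, NULL, if (fix_c0) 1L else 2L, traj,
                       fitted = rep(0, length(vv)), converged = FALSE,
                       n_iter = 0L,
                       message = "all-zero trajectory: initial concentration not estimable")
    return(fit)
  }
  increasing <- all(diff(vv) >= 0) && any(diff(vv) > 0)
  constant <- length(unique(vv)) == 1L
  c0_fixed <- if (fix_c0) mean(vv[tt == min(tt)]) else NA_real_
  if (constant) {
    # zero-range data: the exact least-squares solution is k = 0
    c0_hat <- if (fix_c0) c0_fixed else vv[1L]
    params <- make_params(0, c0_hat)
    return(.fit_result(model_name, params, if (fix_c0) 1L else 2L, traj,
                       fitted = rep(c0_hat, length(vv)), converged = TRUE,
                       n_iter = 0L))
  }
  if (fix_c0) {
    resid_fn <- function(p) vv - c0_fixed * exp(-p[1L] * tt * rate_scale)
    st <- .exp_starts(tt, vv, starts)[, "k", drop = FALSE]
    lower <- 0; upper <- 100
  } else {
    resid_fn <- function(p) vv - p[2L] * exp(-p[1L] * tt * rate_scale)
    st <- .exp_starts(tt, vv, starts)
    lower <- c(0, 1e-9); upper <- c(100, 10 * max(vv))
  }
  best <- .ms_fit(st, resid_fn, lower, upper)
  k_hat <- best$par[[1L]]
  c0_hat <- if (fix_c0) c0_fixed else best$par[[2L]]
  params <- make_params(k_hat, c0_hat)
  fitted <- c0_hat * exp(-k_hat * tt * rate_scale)
  msg <- if (increasing) "trajectory is nondecreasing; first-order decay model inappropriate" else NULL
  .fit_result(model_name, params, if (fix_c0) 1L else 2L, traj, fitted,
              converged = best$converged && !increasing,
              n_iter = best$n_iter, message = msg)
}

#' Fit the first-order ureolysis model
#'
#' Estimates the ureolysis rate coefficient (and by default the initial
#' urea concentration) by bounded multistart nonlinear least squares on
#' `c(t) = c0 * exp(-k t c_x)`. Starting points combine a log-domain
#' regression (log concentration on time, over positive values) with a
#' log-spaced grid of rates; bounds are k in \[0, 100\] per hour and c0
#' positive. Since k and the cell density only enter as a product, `c_x`
#' rescales the reported rate rather than being estimated.
#'
#' @param traj a [trajectory()] with `variable == "urea_gL"` and at least
#'   3 distinct times.
#' @param c_x constant viable-cell density used to express the rate
#'   (default 1: the effective rate is reported).
#' @param fix_c0 fix the initial concentration to the earliest measurement
#'   instead of estimating it.
#' @param starts number of multistart initializations.
#' @return A `kinetic_fit` with [ureolysis_params()], r2, rmse, residuals,
#'   convergence flag and iteration count. Nondecreasing trajectories are
#'   flagged `converged = FALSE` with a diagnostic message rather than
#'   silently returning a meaningless rate.
#' @export
#' @examples
#' p <- ureolysis_params(0.04, 19.99)
#' tt <- c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72)
#' tr <- trajectory("B. licheniformis", "urea_gL", tt, urea_model(tt, p))
#' fit_ureolysis(tr)$params
fit_ureolysis <- function(traj, c_x = 1, fix_c0 = FALSE, starts = 8L) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$variable != "urea_gL")
    stop("fit_ureolysis expects a 'urea_gL' trajectory", call. = FALSE)
  stopifnot(is.numeric(c_x), length(c_x) == 1L, c_x > 0)
  .fit_exponential(traj, rate_scale = c_x, fix_c0 = fix_c0, starts = starts,
                   make_params = function(k, c0)
                     ureolysis_params(k_urea = k, c_urea0 = max(c0, 1e-12), c_x = c_x),
                   model_name = "ureolysis")
}

#' Fit the first-order calcium precipitation model
#'
#' Estimates the Ca2+ removal rate coefficient and (by default) the
#' initial free-calcium concentration from `c(t) = c0 * exp(-k t)`.
#' Steep decays, where the concentration falls orders of magnitude between
#' samples, are handled by the log-domain initialization: a regression of
#' log concentration on time over the positive observations seeds the
#' optimizer near the global optimum.
#'
#' @param traj a [trajectory()] with `variable == "calcium_mgL"` and at
#'   least 3 distinct times.
#' @inheritParams fit_ureolysis
#' @return A `kinetic_fit` with [precipitation_params()].
#' @export
#' @examples
#' p <- precipitation_params(4.84, 1266)
#' tr <- trajectory("B. licheniformis", "calcium_mgL", 0:14,
#'                  ca_model(0:14, p), time_unit = "days")
#' fit_precipitation(tr)$params
fit_precipitation <- function(traj, fix_c0 = FALSE, starts = 8L) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$variable != "calcium_mgL")
    stop("fit_precipitation expects a 'calcium_mgL' trajectory", call. = FALSE)
  .fit_exponential(traj, rate_scale = 1, fix_c0 = fix_c0, starts = starts,
                   make_params = function(k, c0)
                     precipitation_params(k_precipitate = k, c_ca0 = max(c0, 1e-12)),
                   model_name = "precipitation")
}

#' Fit the four-parameter sigmoid model
#'
#' Estimates (a, d, c, b) of `y(t) = d + (a-d)/(1 + (t/c)^b)` by bounded
#' multistart nonlinear least squares. The heuristic start sets a to the
#' earliest observation, d to the latest, c to the time whose observation
#' lies nearest the midpoint (a+d)/2, and sweeps the Hill slope b over a
#' log-spaced ladder; this tames the very steep slopes (b up to ~25) seen
#' in MICP-phase pH trajectories. Bounds keep a and d within one data
#' range of the observations, c in (0, 2 t_max\] and b in (0, 50\].
#'
#' A constant trajectory is returned as the degenerate a = d fit with
#' r2 = 1 by convention (zero residuals against zero variance) and a
#' warning; midpoint and slope are then not identifiable.
#'
#' @param traj a [trajectory()] with variable pH, log_cells or
#'   precipitate_g and at least 5 distinct times.
#' @param starts number of multistart initializations (default 8).
#' @return A `kinetic_fit` with [sigmoid_params()]. If no start converges
#'   the best-found parameters are returned with `converged = FALSE`.
#' @export
#' @examples
#' p <- sigmoid_params(a = 7.19, d = 9.15, c = 3.07, b = 1.37)
#' tt <- c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72)
#' tr <- trajectory("S. pasteurii", "pH", tt, sigmoid_model(tt, p))
#' fit_sigmoid(tr)$params
fit_sigmoid <- function(traj, starts = 8L) {
  stopifnot(inherits(traj, "trajectory"))
  if (!traj$variable %in% c("pH", "log_cells", "precipitate_g"))
    stop("fit_sigmoid expects a pH, log_cells or precipitate_g trajectory",
         call. = FALSE)
  tt <- traj$times
  vv <- traj$values
  if (length(unique(tt)) < 5L)
    stop("need at least 5 distinct time points for a sigmoid fit", call. = FALSE)
  if (length(unique(vv)) == 1L) {
    warning("constant trajectory: returning degenerate a = d fit; ",
            "midpoint and slope are not identifiable", call. = FALSE)
    params <- sigmoid_params(a = vv[1L], d = vv[1L], c = max(max(tt) / 2, 1), b = 1)
    return(.fit_result("sigmoid", params, 4L, traj,
                       fitted = rep(vv[1L], length(vv)),
                       converged = TRUE, n_iter = 0L,
                       message = "degenerate constant fit (a = d)"))
  }
  rng <- diff(range(vv))
  t_max <- max(tt)
  a0 <- vv[which.min(tt)]
  d0 <- vv[which.max(tt)]
  if (a0 == d0) d0 <- if (which.max(abs(vv - a0)) > 1L) vv[which.max(abs(vv - a0))] else a0 + rng
  mid <- (a0 + d0) / 2
  c0 <- tt[which.min(abs(vv - mid))]
  pos_t <- tt[tt > 0]
  if (c0 <= 0) c0 <- if (length(pos_t)) min(pos_t) else 1
  b_ladder <- c(1, 0.5, 2, 5, 10, 15, 25, 40)
  st <- cbind(a = a0, d = d0, c = c0, b = b_ladder[seq_len(min(starts, 8L))])
  if (starts > 8L) {
    extra <- cbind(a = a0, d = d0,
                   c = stats::median(pos_t),
                   b = b_ladder[seq_len(starts - 8L) %% 8L + 1L])
    st <- rbind(st, extra)
  }
  lower <- c(min(vv) - rng, min(vv) - rng, 1e-6, 1e-3)
  upper <- c(max(vv) + rng, max(vv) + rng, 2 * t_max, 50)
  resid_fn <- function(p) vv - .sigmoid(tt, p[1L], p[2L], p[3L], p[4L])
  best <- .ms_fit(st, resid_fn, lower, upper)
  params <- sigmoid_params(a = best$par[[1L]], d = best$par[[2L]],
                           c = best$par[[3L]], b = best$par[[4L]])
  fitted <- sigmoid_model(tt, params)
  msg <- if (!best$converged) "multistart budget exhausted without convergence; best-found parameters returned" else NULL
  .fit_result("sigmoid", params, 4L, traj, fitted,
              converged = best$converged, n_iter = best$n_iter, message = msg)
}

#' Goodness of fit of predictions against observations
#'
#' Computes the coefficient of determination `r2 = 1 - SS_res/SS_tot`
#' (total sum of squares about the observed mean), the root-mean-square
#' error `sqrt(SS_res/n)` and the raw residuals (observed - predicted).
#' When the observations have zero variance, r2 is 1 if the residuals are
#' also (numerically) zero — a model that reproduces constant data exactly
#' — and otherwise undefined, reported as `NaN` with a warning.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return List with `r2`, `rmse`, `residuals`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4)) # r2 = 0.5
goodness_of_fit <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L)
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    tol <- 1e-8 * (abs(mean(observed)) + 1)
    if (all(abs(res) < tol)) {
      r2 <- 1
    } else {
      warning("observations have zero variance but residuals are nonzero; ",
              "r2 is undefined", call. = FALSE)
      r2 <- NaN
    }
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  list(r2 = r2, rmse = sqrt(ss_res / length(res)), residuals = res)
}

#' Replicate-based lack-of-fit F-test
#'
#' Partitions the residual sum of squares of a fitted kinetic model into
#' pure error (within replicated time points) and lack of fit, and tests
#' the lack-of-fit mean square against the pure-error mean square with an
#' F-test. A p-value above 0.05 means the model describes the data as well
#' as replicate scatter allows (an "insignificant" lack of fit).
#'
#' @param traj the fitted [trajectory()]; replication is inferred from
#'   duplicated time points.
#' @param fit the corresponding `kinetic_fit`.
#' @return List with `p_value`, `statistic`, `df` (lack-of-fit and
#'   pure-error degrees of freedom), `ss_lof`, `ss_pe`; or, when the data
#'   carry no replication or too few distinct times, `p_value = NA` with a
#'   message explaining the skip.
#' @export
lack_of_fit_test <- function(traj, fit) {
  stopifnot(inherits(traj, "trajectory"), inherits(fit, "kinetic_fit"))
  tt <- traj$times
  vv <- traj$values
  groups <- split(vv, tt)
  n <- length(vv)
  m <- length(groups)
  df_pe <- n - m
  replicated <- sum(lengths(groups) >= 2L)
  if (df_pe < 1L || replicated < 2L) {
    message("lack-of-fit test skipped: needs >= 2 replicated time points")
    return(list(p_value = NA_real_, statistic = NA_real_, df = c(NA, NA),
                ss_lof = NA_real_, ss_pe = NA_real_))
  }
  df_lof <- m - fit$n_par
  if (df_lof < 1L) {
    message("lack-of-fit test skipped: model uses as many parameters as ",
            "distinct time points")
    return(list(p_value = NA_real_, statistic = NA_real_, df = c(NA, NA),
                ss_lof = NA_real_, ss_pe = NA_real_))
  }
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ss_res <- sum(fit$residuals^2)
  ss_lof <- max(ss_res - ss_pe, 0)
  stat <- (ss_lof / df_lof) / (ss_pe / df_pe)
  p <- stats::pf(stat, df_lof, df_pe, lower.tail = FALSE)
  list(p_value = p, statistic = stat, df = c(lof = df_lof, pe = df_pe),
       ss_lof = ss_lof, ss_pe = ss_pe)
}
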