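#' Known trajectory variable kinds
#' @keywords internal
.trajectory_variables <- c("urea_gL", "pH", "log_cells", "precipitate_g", "calcium_mgL")

# variables that cannot physically be negative
.nonneg_variables <- c("urea_gL", "log_cells", "precipitate_g", "calcium_mgL")

#' Construct a strain x variable time series
#'
#' One trajectory holds the measurements of a single variable for a single
#' strain: urea concentration (g/L), pH, viable cells (log CFU/mL),
#' precipitate mass (g per 100 mL culture) or free calcium (mg/L).
#' Ureolysis-phase experiments are sampled in hours, MICP-phase
#' experiments in days; the declared `time_unit` disambiguates pH series,
#' which occur in both phases.
#'
#' @param strain strain label.
#' @param variable one of `urea_gL`, `pH`, `log_cells`, `precipitate_g`,
#'   `calcium_mgL`.
#' @param times nondecreasing nonnegative sampling times.
#' @param values measurements, same length as `times`.
#' @param time_unit `"hours"` or `"days"`.
#' @param replicates optional replicate index per point.
#' @return An object of class `trajectory`.
#' @export
#' @examples
#' trajectory("S. pasteurii", "urea_gL", c(0, 24, 72), c(19.4, 1.76, 0.015))
trajectory <- function(strain, variable, times, values,
                       time_unit = c("hours", "days"), replicates = NULL) {
  time_unit <- match.arg(time_unit)
  variable <- match.arg(variable, .trajectory_variables)
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  if (is.unsorted(times)) stop("times must be nondecreasing", call. = FALSE)
  if (variable %in% .nonneg_variables && any(values < 0))
    stop(sprintf("'%s' values must be nonnegative", variable), call. = FALSE)
  if (!is.null(replicates)) stopifnot(length(replicates) == length(times))
  structure(list(strain = as.character(strain), variable = variable,
                 time_unit = time_unit, times = as.numeric(times),
                 values = as.numeric(values), replicates = replicates),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$strain, " / ", x$variable, ": ",
      length(x$times), " points over ", min(x$times), "-", max(x$times),
      " ", x$time_unit, "\n", sep = "")
  invisible(x)
}

#' Read trajectories from a long-format CSV
#'
#' The dialect has columns `strain,variable,time,time_unit,value` and an
#' optional `replicate`. Returns a list of [trajectory()] objects, one per
#' strain x variable x time-unit combination found in the file.
#'
#' @param path CSV file path.
#' @return Named list of trajectories (`strain.variable.time_unit`).
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "variable", "time", "time_unit", "value")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  key <- interaction(df$strain, df$variable, df$time_unit, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time), , drop = FALSE]
    trajectory(g$strain[1L], g$variable[1L], g$time, g$value,
               time_unit = g$time_unit[1L],
               replicates = if ("replicate" %in% names(g)) g$replicate else NULL)
  })
  out
}

#' Write trajectories to a long-format CSV
#'
#' @param trajs a trajectory or list of trajectories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    df <- data.frame(strain = tr$strain, variable = tr$variable,
                     time = tr$times, time_unit = tr$time_unit,
                     value = tr$values)
    if (!is.null(tr$replicates)) df$replicate <- tr$replicates
    df
  })
  has_rep <- vapply(rows, function(d) "replicate" %in% names(d), TRUE)
  if (any(has_rep) && !all(has_rep))
    rows <- lapply(rows, function(d) { if (!"replicate" %in% names(d)) d$replicate <- 1L; d })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
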