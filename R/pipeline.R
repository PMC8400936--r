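# slot each trajectory into its place in a strain's kinetic profile
.profile_slot <- function(variable, time_unit) {
  switch(paste(variable, time_unit),
         "urea_gL hours" = "ureolysis",
         "pH hours" = "ph_ureolysis",
         "log_cells hours" = "cells",
         "precipitate_g days" = "precipitate_amount",
         "pH days" = "ph_micp",
         "calcium_mgL days" = "calcium",
         NA_character_)
}

.slot_fitter <- function(slot) {
  switch(slot,
         ureolysis = function(tr, c_x, fix_c0) fit_ureolysis(tr, c_x = c_x, fix_c0 = fix_c0),
         calcium = function(tr, c_x, fix_c0) fit_precipitation(tr, fix_c0 = fix_c0),
         function(tr, c_x, fix_c0) fit_sigmoid(tr))
}

#' Fit the full kinetic profile of one strain
#'
#' Runs the applicable model fit for every trajectory of one strain: the
#' first-order ureolysis model on urea, sigmoids on ureolysis-phase pH and
#' cell counts and on MICP-phase precipitate mass and pH, and the
#' first-order depletion model on free calcium. Missing variables are
#' skipped with a notice.
#'
#' @param trajs list of [trajectory()] objects, all for the same strain.
#' @param c_x viable-cell density passed to [fit_ureolysis()].
#' @param fix_c0 passed to the exponential fits.
#' @return An object of class `strain_kinetic_profile`: the six fit slots
#'   (`ureolysis`, `ph_ureolysis`, `cells`, `precipitate_amount`,
#'   `ph_micp`, `calcium`; absent ones `NULL`) plus `derived` summaries
#'   from [derive_summaries()].
#' @export
fit_strain_profile <- function(trajs, c_x = 1, fix_c0 = FALSE) {
  stopifnot(length(trajs) >= 1L)
  strain <- trajs[[1L]]$strain
  slots <- c("ureolysis", "ph_ureolysis", "cells", "precipitate_amount",
             "ph_micp", "calcium")
  prof <- stats::setNames(vector("list", length(slots)), slots)
  for (tr in trajs) {
    stopifnot(identical(tr$strain, strain))
    slot <- .profile_slot(tr$variable, tr$time_unit)
    if (is.na(slot)) next
    fitter <- .slot_fitter(slot)
    prof[[slot]] <- tryCatch(fitter(tr, c_x, fix_c0),
                             error = function(e) {
                               message(sprintf("fit skipped for %s / %s: %s",
                                               strain, slot, conditionMessage(e)))
                               NULL
                             })
  }
  out <- structure(c(list(strain = strain), prof, list(derived = NULL)),
                   class = "strain_kinetic_profile")
  out$derived <- derive_summaries(out)
  out
}

#' @export
print.strain_kinetic_profile <- function(x, ...) {
  cat("<strain_kinetic_profile> ", x$strain, "\n", sep = "")
  for (s in c("ureolysis", "ph_ureolysis", "cells", "precipitate_amount",
              "ph_micp", "calcium")) {
    f <- x[[s]]
    cat("  ", format(s, width = 18),
        if (is.null(f)) "(absent)" else paste0("r2 = ", signif(f$r2, 4)), "\n",
        sep = "")
  }
  invisible(x)
}

#' Derived process summaries for one strain
#'
#' Computes headline quantities from a fitted profile: the percent
#' reduction of free calcium by `t_report` days (closed form from the
#' depletion rate), the pH rise `d - a` of the MICP-phase pH sigmoid, and
#' the percent urea remaining after `t_end_ureolysis` hours,
#' `100 exp(-k t c_x)` — which depends on the assumed cell density through
#' the product `k c_x`. Summaries whose underlying fit is absent or
#' unconverged are reported as `NA`.
#'
#' @param profile a `strain_kinetic_profile`.
#' @param t_end_ureolysis end of the ureolysis experiment in hours.
#' @param t_report reporting time for calcium reduction, in days.
#' @return Named list: `percent_ca_reduction_24h`, `ph_rise`,
#'   `urea_residual_percent`.
#' @export
derive_summaries <- function(profile, t_end_ureolysis = 72, t_report = 1) {
  stopifnot(inherits(profile, "strain_kinetic_profile"))
  ok <- function(f) !is.null(f) && isTRUE(f$converged) && !is.null(f$params)
  ca <- if (ok(profile$calcium))
    percent_reduction(profile$calcium$params, t_report) else NA_real_
  rise <- if (ok(profile$ph_micp))
    profile$ph_micp$params$d - profile$ph_micp$params$a else NA_real_
  resid <- if (ok(profile$ureolysis)) {
    p <- profile$ureolysis$params
    100 * exp(-p$k_urea * t_end_ureolysis * p$c_x)
  } else NA_real_
  list(percent_ca_reduction_24h = ca, ph_rise = rise,
       urea_residual_percent = resid)
}

# one report row per fitted strain x variable slot
.report_row <- function(strain, slot, fit) {
  row <- data.frame(strain = strain, variable = slot,
                    k_Urea = NA_real_, c_Urea = NA_real_,
                    a = NA_real_, d = NA_real_, c = NA_real_, b = NA_real_,
                    k_precipitate = NA_real_, c_Ca = NA_real_,
                    r2 = fit$r2, rmse = fit$rmse, converged = fit$converged)
  p <- fit$params
  if (inherits(p, "ureolysis_params")) {
    row$k_Urea <- p$k_urea; row$c_Urea <- p$c_urea0
  } else if (inherits(p, "sigmoid_params")) {
    row$a <- p$a; row$d <- p$d; row$c <- p$c; row$b <- p$b
  } else if (inherits(p, "precipitation_params")) {
    row$k_precipitate <- p$k_precipitate; row$c_Ca <- p$c_ca0
  }
  row
}

#' Assemble a coefficient report from fitted profiles
#'
#' @param profiles list of `strain_kinetic_profile` objects.
#' @return Data frame, one row per strain x fitted variable, with the
#'   coefficient columns `k_Urea`, `c_Urea`, `a`, `d`, `c`, `b`,
#'   `k_precipitate`, `c_Ca` plus `r2`, `rmse`, `converged`.
#' @export
kinetic_report <- function(profiles) {
  slots <- c("ureolysis", "ph_ureolysis", "cells", "precipitate_amount",
             "ph_micp", "calcium")
  rows <- list()
  for (pr in profiles) {
    stopifnot(inherits(pr, "strain_kinetic_profile"))
    for (s in slots) {
      if (!is.null(pr[[s]])) rows[[length(rows) + 1L]] <- .report_row(pr$strain, s, pr[[s]])
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Run the full scoring and fitting pipeline
#'
#' Orchestrates the analysis over a data bundle: optional isolate scoring
#' from an assay panel, all applicable kinetic fits per strain, derived
#' summaries, and report files. The configuration is validated before any
#' computation; a missing variable for a requested fit is logged and
#' skipped, never silently absent.
#'
#' @param config one of: a [synthetic_config()] (trajectories are
#'   generated in memory); a path to a JSON file; or a list. The JSON/list
#'   form accepts fields `trajectory_dir` (directory of long-format CSVs)
#'   or `trajectory_files`, optional `panel` (assay CSV path), `weights`,
#'   `top_n`, `c_x`, `fix_c0`, `synthetic` (a nested
#'   [synthetic_config()]-shaped spec) and `seed`.
#' @param out_dir directory for `report.csv`, `report.json`, `run.log` and
#'   (when a panel is scored) `scores.csv`.
#' @return Invisibly, a list with `report` (data frame), `profiles`,
#'   `scores` (or `NULL`) and `log` (character).
#' @export
run_pipeline <- function(config, out_dir) {
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  # -- resolve and validate configuration before computing anything
  c_x <- 1; fix_c0 <- FALSE; panel <- NULL; top_n <- NULL; weights <- NULL
  if (inherits(config, "synthetic_config")) {
    scfg <- config
    seed <- scfg$seed
    trajs <- NULL
  } else {
    if (is.character(config)) {
      if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (!is.list(config)) stop("malformed config: expected a list or JSON path", call. = FALSE)
    seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
    if (!is.null(config$c_x)) c_x <- config$c_x
    if (!is.null(config$fix_c0)) fix_c0 <- isTRUE(config$fix_c0)
    if (!is.null(config$top_n)) top_n <- as.integer(config$top_n)
    if (!is.null(config$weights)) weights <- as.numeric(config$weights)
    scfg <- NULL
    trajs <- NULL
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      scfg <- synthetic_config(
        profiles = if (is.null(sc$profiles)) strain_profiles() else as_strain_profiles(sc$profiles),
        schedule_ureolysis = if (is.null(sc$schedule_ureolysis)) c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72) else sc$schedule_ureolysis,
        schedule_micp = if (is.null(sc$schedule_micp)) 0:14 else sc$schedule_micp,
        noise = if (is.null(sc$noise)) c(urea_gL = 0) else unlist(sc$noise),
        seed = if (is.null(sc$seed)) seed else sc$seed,
        truncate_at_zero = if (is.null(sc$truncate_at_zero)) TRUE else sc$truncate_at_zero)
    } else {
      files <- config$trajectory_files
      if (!is.null(config$trajectory_dir)) {
        if (!dir.exists(config$trajectory_dir))
          stop("trajectory_dir not found: ", config$trajectory_dir, call. = FALSE)
        files <- list.files(config$trajectory_dir, pattern = "\\.csv$",
                            full.names = TRUE)
      }
      if (is.null(files) || !length(files))
        stop("malformed config: no trajectory source given", call. = FALSE)
      missing <- files[!file.exists(files)]
      if (length(missing))
        stop("trajectory file(s) not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
      trajs <- unlist(lapply(files, read_trajectories), recursive = FALSE)
    }
    panel <- config$panel
    if (!is.null(panel) && !file.exists(panel))
      stop("panel file not found: ", panel, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  note("run_pipeline: seed = %d, micpkin %s", seed,
       as.character(utils::packageVersion("micpkin")))

  # -- synthetic generation, if configured
  if (!is.null(scfg)) {
    trajs <- list()
    for (s in names(scfg$profiles)) {
      for (v in .trajectory_variables) {
        trajs <- c(trajs, list(simulate_trajectory(scfg, s, v, phase = "ureolysis")))
        if (v == "pH")
          trajs <- c(trajs, list(simulate_trajectory(scfg, s, v, phase = "micp")))
      }
    }
    note("generated %d synthetic trajectories for %d strains (seed %d)",
         length(trajs), length(scfg$profiles), scfg$seed)
  }

  # -- scoring stage
  scores <- NULL
  if (!is.null(panel)) {
    pan <- read_assay_panel(panel, weights = weights)
    scores <- standard_score(pan)
    if (!is.null(top_n))
      note("selected top %d isolates: %s", top_n,
           paste(select_top(scores, n = top_n), collapse = ", "))
    write_score_result(scores, file.path(out_dir, "scores.csv"))
    note("scores written for %d isolates", length(scores$scores))
  }

  # -- fitting stage
  strains <- unique(vapply(trajs, function(tr) tr$strain, character(1)))
  profiles <- lapply(strains, function(s) {
    sub <- Filter(function(tr) tr$strain == s, trajs)
    withCallingHandlers(
      fit_strain_profile(sub, c_x = c_x, fix_c0 = fix_c0),
      message = function(m) {
        log_lines <<- c(log_lines, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  })
  names(profiles) <- strains
  slots <- c("ureolysis", "ph_ureolysis", "cells", "precipitate_amount",
             "ph_micp", "calcium")
  for (pr in profiles) {
    for (s in slots) {
      if (is.null(pr[[s]])) {
        note("%s: no %s trajectory in input; fit skipped", pr$strain, s)
      } else if (!isTRUE(pr[[s]]$converged)) {
        note("%s: %s fit did not converge (%s)", pr$strain, s,
             if (is.null(pr[[s]]$message)) "no diagnostic" else pr[[s]]$message)
      }
    }
  }

  report <- kinetic_report(profiles)
  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  json <- list(
    seed = seed,
    strains = lapply(profiles, function(pr) {
      fits <- lapply(slots, function(s) {
        f <- pr[[s]]
        if (is.null(f)) return(NULL)
        list(params = unclass(f$params), r2 = f$r2, rmse = f$rmse,
             converged = f$converged)
      })
      names(fits) <- slots
      list(fits = fits[!vapply(fits, is.null, TRUE)], derived = pr$derived)
    }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  conv <- sum(report$converged)
  note("report written: %d fits (%d converged) across %d strains",
       nrow(report), conv, length(profiles))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(report = report, profiles = profiles, scores = scores,
                 log = log_lines))
}
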