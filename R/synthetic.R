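#' Built-in kinetic profiles for seven MICP strains
#'
#' Published regression coefficients for the two reference strains
#' (ureolytic *Sporosarcina pasteurii* DSM 33 and non-ureolytic
#' *Bacillus pseudofirmus* DSM 8715) and the five selected soil isolates
#' (*B. muralis*, *B. lentus*, *B. simplex*, *B. firmus*,
#' *B. licheniformis*). Each strain carries six parameter sets: the
#' first-order ureolysis coefficients (per hour, normalized cell unit),
#' the ureolysis-phase pH and viable-cell sigmoids (hours), the MICP-phase
#' precipitate-mass and pH sigmoids (days) and the first-order free-calcium
#' depletion coefficients (per day). These defaults drive the synthetic
#' generator so that every pipeline stage can be validated by parameter
#' recovery.
#'
#' @return Named list, one entry per strain, each with elements
#'   `ureolysis`, `ph_ureolysis`, `cells`, `precipitate`, `ph_micp`,
#'   `calcium`.
#' @export
#' @examples
#' strain_profiles()[["B. licheniformis"]]$ureolysis
strain_profiles <- function() {
  strains <- c("S. pasteurii", "B. pseudofirmus", "B. muralis", "B. lentus",
               "B. simplex", "B. firmus", "B. licheniformis")
  k_urea  <- c(0.10, 0.00, 0.02, 0.01, 0.03, 0.03, 0.04)
  c_urea  <- c(19.45, 19.878, 19.95, 19.42, 19.55, 19.99, 19.99)
  ph_u_d  <- c(9.15, 7.24, 8.87, 8.14, 9.2, 9.14, 8.812)
  ph_u_a  <- c(7.19, 7.19, 7.27, 7.36, 7.45, 7.19, 7.2)
  ph_u_c  <- c(3.07, 5.54, 8.13, 13.85, 15.35, 12.33, 11.40)
  ph_u_b  <- c(1.37, 5.28, 7.43, 2.99, 4.01, 2.37, 15.30)
  cell_d  <- c(9.90, 6.68, 6.567, 8.11, 8.18, 8.6, 11.66)
  cell_a  <- c(5.55, 5.05, 5.61, 6.3, 5.75, 6.2, 5.03)
  cell_c  <- c(30.00, 20.89, 18.71, 30.00, 9.16, 15.20, 32.15)
  cell_b  <- c(0.79, 1.96, 4.49, 1.78, 4.93, 2.95, 0.8)
  prec_d  <- c(0.46, 0.001, 0.57, 0.21, 0.56, 0.47, 0.51)
  prec_a  <- c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001)
  prec_c  <- c(1.32, 5.78, 5.88, 2.98, 3.69, 3.04, 2.82)
  prec_b  <- c(4.09, 2.56, 2.06, 5.97, 1.22, 3.75, 6.00)
  ph_m_d  <- c(8.97, 7.20, 8.31, 8.53, 9.28, 9.15, 9.37)
  ph_m_a  <- c(7.23, 7.23, 7.22, 7.23, 7.23, 7.23, 7.21)
  ph_m_c  <- c(0.50, 1.78, 1.07, 0.89, 1.01, 0.95, 1.01)
  ph_m_b  <- c(19.17, 19.06, 24.99, 22.89, 19.00, 25.00, 24.55)
  k_prec  <- c(0.84, 0.01, 0.251, 0.07, 0.36, 0.45, 4.84)
  c_ca    <- c(1282.34, 1237.18, 1294.89, 1146.27, 1171.96, 1340.89, 1266.00)
  out <- lapply(seq_along(strains), function(i) {
    list(ureolysis   = ureolysis_params(k_urea[i], c_urea[i]),
         ph_ureolysis = sigmoid_params(ph_u_a[i], ph_u_d[i], ph_u_c[i], ph_u_b[i]),
         cells       = sigmoid_params(cell_a[i], cell_d[i], cell_c[i], cell_b[i]),
         precipitate = sigmoid_params(prec_a[i], prec_d[i], prec_c[i], prec_b[i]),
         ph_micp     = sigmoid_params(ph_m_a[i], ph_m_d[i], ph_m_c[i], ph_m_b[i]),
         calcium     = precipitation_params(k_prec[i], c_ca[i]))
  })
  names(out) <- strains
  out
}

#' Default sampling schedules
#'
#' The ureolysis-phase experiment samples at 0, 1, 4, 6, 8, 10, 12, 24,
#' 36, 48, 60 and 72 hours; the MICP-phase experiment samples daily from
#' day 0 to day 14.
#' @name schedules
#' @export
schedule_ureolysis <- function() c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72)

#' @rdname schedules
#' @export
schedule_micp <- function() 0:14

#' Configuration for the synthetic trajectory generator
#'
#' @param profiles strain kinetic profiles, as from [strain_profiles()].
#' @param schedule_ureolysis sampling times in hours for ureolysis-phase
#'   variables (urea, pH, cells).
#' @param schedule_micp sampling times in days for MICP-phase variables
#'   (precipitate, pH, calcium).
#' @param noise named per-variable additive Gaussian standard deviations
#'   (names among `urea_gL`, `pH`, `log_cells`, `precipitate_g`,
#'   `calcium_mgL`); default 0 = noiseless.
#' @param seed integer seed; each (strain, variable, phase) stream is
#'   seeded deterministically from it, so identical configs reproduce
#'   byte-identical data.
#' @param truncate_at_zero clamp concentrations/masses at zero after
#'   adding noise (default TRUE).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(profiles = strain_profiles(),
                             schedule_ureolysis = c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72),
                             schedule_micp = 0:14,
                             noise = c(urea_gL = 0, pH = 0, log_cells = 0,
                                       precipitate_g = 0, calcium_mgL = 0),
                             seed = 1L,
                             truncate_at_zero = TRUE) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  full_noise <- c(urea_gL = 0, pH = 0, log_cells = 0, precipitate_g = 0,
                  calcium_mgL = 0)
  if (length(noise)) {
    stopifnot(!is.null(names(noise)) || length(noise) == 5L)
    if (is.null(names(noise))) names(noise) <- names(full_noise)
    stopifnot(all(names(noise) %in% names(full_noise)), all(noise >= 0))
    full_noise[names(noise)] <- noise
  }
  stopifnot(!is.unsorted(schedule_ureolysis), !is.unsorted(schedule_micp),
            all(schedule_ureolysis >= 0), all(schedule_micp >= 0))
  for (s in names(profiles)) {
    need <- c("ureolysis", "ph_ureolysis", "cells", "precipitate", "ph_micp",
              "calcium")
    if (!all(need %in% names(profiles[[s]])))
      stop(sprintf("strain '%s' has an incomplete kinetic profile", s),
           call. = FALSE)
  }
  structure(list(profiles = profiles,
                 schedule_ureolysis = as.numeric(schedule_ureolysis),
                 schedule_micp = as.numeric(schedule_micp),
                 noise = full_noise,
                 seed = as.integer(seed),
                 truncate_at_zero = isTRUE(truncate_at_zero)),
            class = "synthetic_config")
}

#' Rebuild strain profiles from a plain-list (e.g. JSON) representation
#'
#' @param x named list per strain with numeric-field sublists `ureolysis`,
#'   `ph_ureolysis`, `cells`, `precipitate`, `ph_micp`, `calcium`.
#' @return Profiles in the form of [strain_profiles()].
#' @export
as_strain_profiles <- function(x) {
  stopifnot(is.list(x), length(x) >= 1L)
  lapply(x, function(p) {
    if (inherits(p$ureolysis, "kinetic_params")) return(p)
    list(ureolysis = ureolysis_params(p$ureolysis$k_urea, p$ureolysis$c_urea0,
                                      if (is.null(p$ureolysis$c_x)) 1 else p$ureolysis$c_x),
         ph_ureolysis = sigmoid_params(p$ph_ureolysis$a, p$ph_ureolysis$d,
                                       p$ph_ureolysis$c, p$ph_ureolysis$b),
         cells = sigmoid_params(p$cells$a, p$cells$d, p$cells$c, p$cells$b),
         precipitate = sigmoid_params(p$precipitate$a, p$precipitate$d,
                                      p$precipitate$c, p$precipitate$b),
         ph_micp = sigmoid_params(p$ph_micp$a, p$ph_micp$d, p$ph_micp$c,
                                  p$ph_micp$b),
         calcium = precipitation_params(p$calcium$k_precipitate,
                                        p$calcium$c_ca0))
  })
}

# deterministic small hash of a label, for per-stream seeding
.label_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1000003L
  (as.integer(seed) %% 2000000L) * 1000L + h %% 1000L
}

#' Simulate one strain x variable trajectory
#'
#' Evaluates the strain's kinetic model on the phase schedule and adds
#' i.i.d. Gaussian noise with the configured per-variable standard
#' deviation, clamping concentration/mass values at zero when
#' `truncate_at_zero` is set. With zero noise the output equals the closed
#' form exactly; with a fixed config the output is reproducible.
#'
#' @param config a [synthetic_config()].
#' @param strain strain label present in `config$profiles`.
#' @param variable one of `urea_gL`, `pH`, `log_cells`, `precipitate_g`,
#'   `calcium_mgL`.
#' @param phase which experimental phase a pH trajectory belongs to:
#'   `"ureolysis"` (hours) or `"micp"` (days). Ignored for variables that
#'   occur in only one phase.
#' @return A [trajectory()].
#' @export
#' @examples
#' cfg <- synthetic_config()
#' simulate_trajectory(cfg, "B. licheniformis", "urea_gL")
simulate_trajectory <- function(config, strain, variable,
                                phase = c("ureolysis", "micp")) {
  stopifnot(inherits(config, "synthetic_config"))
  phase <- match.arg(phase)
  if (!strain %in% names(config$profiles))
    stop(sprintf("unknown strain '%s'", strain), call. = FALSE)
  variable <- match.arg(variable, .trajectory_variables)
  prof <- config$profiles[[strain]]
  if (variable %in% c("urea_gL", "log_cells")) phase <- "ureolysis"
  if (variable %in% c("precipitate_g", "calcium_mgL")) phase <- "micp"
  if (phase == "ureolysis") {
    tt <- config$schedule_ureolysis
    unit <- "hours"
  } else {
    tt <- config$schedule_micp
    unit <- "days"
  }
  mu <- switch(variable,
    urea_gL = urea_model(tt, prof$ureolysis),
    pH = sigmoid_model(tt, if (phase == "ureolysis") prof$ph_ureolysis else prof$ph_micp),
    log_cells = sigmoid_model(tt, prof$cells),
    precipitate_g = sigmoid_model(tt, prof$precipitate),
    calcium_mgL = ca_model(tt, prof$calcium))
  sigma <- config$noise[[variable]]
  vals <- mu
  if (sigma > 0) {
    seed_i <- .label_seed(config$seed, paste(strain, variable, phase))
    vals <- withr_local_seed(seed_i, mu + stats::rnorm(length(mu), 0, sigma))
  }
  if (config$truncate_at_zero && variable %in% .nonneg_variables)
    vals <- pmax(vals, 0)
  trajectory(strain, variable, tt, vals, time_unit = unit)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an assay panel with a planted top group
#'
#' Emulates the screening stage: `n_isolates` isolates measured on the
#' nine MICP assay variables, with a designated subset of `n_top` isolates
#' drawing near the per-variable maxima on every assay (isolates able to
#' precipitate through both the ureolytic and the heterotrophic pathway)
#' and the remainder drawing from a broad sub-maximal distribution. Under
#' equal weights the planted group therefore occupies the top standard-score
#' ranks. Quantitative assays use realistic ranges (sporulation rate in
#' percent, pH optimum 7-9.5); qualitative assays are encoded as continuous
#' intensities on a 0-2 scale.
#'
#' @param n_isolates total number of isolates (>= 2).
#' @param n_top size of the planted top group (0 disables planting).
#' @param seed integer seed.
#' @return An [assay_panel()] with equal weights; the planted isolates are
#'   named `TOP_1 ... TOP_n`.
#' @export
#' @examples
#' pan <- simulate_assay_panel(43, 5, seed = 1)
#' head(standard_score(pan)$ranking)
simulate_assay_panel <- function(n_isolates = 43L, n_top = 5L, seed = 1L) {
  stopifnot(n_isolates >= 2L, n_top >= 0L, n_top <= n_isolates)
  lo <- c(SR = 0, pH = 7, UAG = 0, UAC = 0, UBT = 0, UBC = 0, UBCA = 0,
          MUC = 0, MEC = 0)
  hi <- c(SR = 100, pH = 9.5, UAG = 2, UAC = 2, UBT = 2, UBC = 2, UBCA = 2,
          MUC = 2, MEC = 2)
  p <- length(lo)
  raw <- withr_local_seed(as.integer(seed), {
    m <- matrix(NA_real_, n_isolates, p)
    for (j in seq_len(p)) {
      # bulk isolates span the lower 85% of the assay range; the planted
      # group sits in the top 8%, guaranteeing strict rank separation
      m[, j] <- stats::runif(n_isolates, lo[j], lo[j] + 0.85 * (hi[j] - lo[j]))
      if (n_top > 0L)
        m[seq_len(n_top), j] <- stats::runif(n_top, lo[j] + 0.92 * (hi[j] - lo[j]), hi[j])
    }
    m
  })
  ids <- c(if (n_top > 0L) paste0("TOP_", seq_len(n_top)),
           paste0("ISO_", seq_len(n_isolates - n_top)))
  assay_panel(raw, isolate_ids = ids, variables = names(lo))
}

#' Write a synthetic fixture bundle
#'
#' Emits one long-format trajectory CSV per strain x variable (the two pH
#' phases share the pH file, distinguished by `time_unit`) plus the
#' generating configuration as JSON, forming a complete on-disk test
#' fixture for the fitting and reporting stages.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  paths <- character(0)
  for (s in names(config$profiles)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", s)
    for (v in .trajectory_variables) {
      trs <- if (v == "pH") {
        list(simulate_trajectory(config, s, v, phase = "ureolysis"),
             simulate_trajectory(config, s, v, phase = "micp"))
      } else {
        list(simulate_trajectory(config, s, v))
      }
      f <- file.path(out_dir, paste0(slug, "__", v, ".csv"))
      write_trajectories(trs, f)
      paths <- c(paths, f)
    }
  }
  cfg_json <- file.path(out_dir, "config.json")
  cfg <- list(
    strains = names(config$profiles),
    profiles = lapply(config$profiles, function(p) lapply(p, unclass)),
    schedule_ureolysis = config$schedule_ureolysis,
    schedule_micp = config$schedule_micp,
    noise = as.list(config$noise),
    seed = config$seed,
    truncate_at_zero = config$truncate_at_zero)
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, cfg_json)
  invisible(paths)
}
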