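#' Canonical MICP assay variable names
#'
#' The nine assay variables scored when screening isolates for MICP
#' potential: sporulation rate (SR), optimal pH growth value (pH), growth
#' on urea agar (UAG), urea agar color change (UAC), urea broth turbidity
#' (UBT), urea broth color change (UBC), precipitation on CaCl2 addition
#' to inoculated urea broth (UBCA), CaCO3 formation on urea-CaCl2 medium
#' (MUC), and CaCO3 formation on yeast-extract-CaCl2 medium (MEC).
#' Qualitative assays are pre-encoded numerically (e.g. ordinal 0 = none,
#' 1 = weak, 2 = strong), a coding declared with the panel rather than
#' hidden in the scoring.
#'
#' @export
micp_assays <- c("SR", "pH", "UAG", "UAC", "UBT", "UBC", "UBCA", "MUC", "MEC")

#' Construct an assay panel
#'
#' Bundles per-isolate raw assay values with per-variable weights and
#' polarities for standard-score ranking. Weights default to equal and are
#' rescaled to sum to 1; polarity +1 marks a larger-is-better variable,
#' -1 a smaller-is-better one (all nine MICP assays are larger-is-better
#' by default).
#'
#' @param raw numeric matrix or data frame, one row per isolate and one
#'   column per assay variable (qualitative assays pre-encoded to numbers).
#' @param isolate_ids character vector of isolate identifiers; defaults to
#'   the rownames of `raw`.
#' @param variables assay names; defaults to the colnames of `raw` or, when
#'   the panel has nine unnamed columns, to [micp_assays].
#' @param weights nonnegative per-variable weights; rescaled to sum to 1.
#' @param polarity vector of +1/-1 per variable.
#' @return An object of class `assay_panel`.
#' @export
#' @examples
#' m <- matrix(c(2, 5, 8, 1, 2, 4), nrow = 3,
#'             dimnames = list(c("I1", "I2", "I3"), c("SR", "pH")))
#' assay_panel(m)
assay_panel <- function(raw, isolate_ids = rownames(raw), variables = colnames(raw),
                        weights = NULL, polarity = NULL) {
  raw <- as.matrix(raw)
  if (length(raw) == 0L) stop("empty assay panel", call. = FALSE)
  if (is.null(variables)) {
    variables <- if (ncol(raw) == length(micp_assays)) micp_assays
                 else paste0("V", seq_len(ncol(raw)))
  }
  if (is.null(isolate_ids)) isolate_ids <- paste0("isolate_", seq_len(nrow(raw)))
  if (!is.numeric(raw)) {
    bad <- which(!vapply(as.vector(raw), function(x) is.numeric(x) || !is.na(suppressWarnings(as.numeric(x))), TRUE))[1L]
    ij <- arrayInd(bad, dim(raw))
    stop(sprintf("non-numeric assay value for isolate '%s', variable '%s'",
                 isolate_ids[ij[1L]], variables[ij[2L]]), call. = FALSE)
  }
  if (anyNA(raw)) {
    ij <- arrayInd(which(is.na(raw))[1L], dim(raw))
    stop(sprintf("missing assay value for isolate '%s', variable '%s'",
                 isolate_ids[ij[1L]], variables[ij[2L]]), call. = FALSE)
  }
  p <- ncol(raw)
  stopifnot(length(isolate_ids) == nrow(raw), length(variables) == p)
  if (is.null(weights)) weights <- rep(1 / p, p)
  stopifnot(is.numeric(weights), length(weights) == p)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  weights <- weights / sum(weights)
  if (is.null(polarity)) polarity <- rep(1L, p)
  stopifnot(length(polarity) == p, all(polarity %in% c(-1, 1)))
  dimnames(raw) <- list(isolate_ids, variables)
  structure(list(isolate_ids = as.character(isolate_ids),
                 variables = as.character(variables),
                 raw = raw,
                 weights = stats::setNames(weights, variables),
                 polarity = stats::setNames(as.integer(polarity), variables)),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("<assay_panel> ", nrow(x$raw), " isolates x ", ncol(x$raw),
      " variables (", paste(x$variables, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Min-max normalize an assay panel
#'
#' Rescales each assay column to \[0, 1\] by subtracting its minimum and
#' dividing by its range, so the best-performing isolate on a variable
#' scores 1 and the worst 0. Columns with negative polarity are reflected
#' (`1 - x`) after rescaling. A constant (zero-range) column carries no
#' discriminating information and is mapped to all zeros with a warning.
#'
#' @param panel an [assay_panel()].
#' @return Numeric matrix of normalized scores in \[0, 1\], same dimnames
#'   as `panel$raw`.
#' @export
#' @examples
#' pan <- assay_panel(matrix(c(2, 5, 8), ncol = 1,
#'                    dimnames = list(NULL, "SR")))
#' normalize_scores(pan) # 0, 0.5, 1
normalize_scores <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  raw <- panel$raw
  out <- raw
  for (j in seq_len(ncol(raw))) {
    rng <- range(raw[, j])
    if (rng[1L] == rng[2L]) {
      warning(sprintf("assay '%s' is constant across isolates; normalized to 0",
                      panel$variables[j]), call. = FALSE)
      out[, j] <- 0
    } else {
      z <- (raw[, j] - rng[1L]) / (rng[2L] - rng[1L])
      out[, j] <- if (panel$polarity[j] < 0) 1 - z else z
    }
  }
  out
}

#' Standard score of each isolate
#'
#' The standard score (SS) of an isolate is the weighted sum of its
#' min-max normalized assay values,
#' \deqn{SS = \sum_i w_i \bar{x}_i,}
#' with weights summing to 1 so SS lies in \[0, 1\]. An SS near 1 marks an
#' isolate close to optimal on every assay simultaneously; SS = 1 exactly
#' when the isolate attains the column optimum of every variable. Ranking
#' is by descending SS with ties broken stably by input order.
#'
#' @param panel an [assay_panel()].
#' @return An object of class `score_result` with elements `normalized`
#'   (matrix in \[0,1\]), `scores` (named per-isolate SS), `ranking`
#'   (isolate ids by descending SS) and `weights`.
#' @export
#' @examples
#' m <- matrix(c(2, 5, 8, 1, 2, 4), nrow = 3,
#'             dimnames = list(c("I1", "I2", "I3"), c("SR", "pH")))
#' standard_score(assay_panel(m))
standard_score <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  norm <- normalize_scores(panel)
  scores <- drop(norm %*% panel$weights)
  names(scores) <- panel$isolate_ids
  ord <- order(-scores, seq_along(scores))
  structure(list(normalized = norm,
                 scores = scores,
                 ranking = panel$isolate_ids[ord],
                 weights = panel$weights),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("<score_result> ", length(x$scores), " isolates; top: ",
      x$ranking[1L], " (SS = ", signif(max(x$scores), 4), ")\n", sep = "")
  invisible(x)
}

#' Select top-ranked isolates
#'
#' Picks either the `n` highest-scoring isolates or all isolates whose
#' standard score meets `threshold`. Ordering follows the stable ranking
#' of [standard_score()].
#'
#' @param result a `score_result` from [standard_score()].
#' @param n number of isolates to keep (mutually exclusive with
#'   `threshold`).
#' @param threshold minimum SS to keep.
#' @return Character vector of selected isolate ids, in rank order.
#' @export
#' @examples
#' m <- matrix(c(2, 5, 8, 1, 2, 4), nrow = 3,
#'             dimnames = list(c("I1", "I2", "I3"), c("SR", "pH")))
#' select_top(standard_score(assay_panel(m)), n = 2)
select_top <- function(result, n = NULL, threshold = NULL) {
  stopifnot(inherits(result, "score_result"))
  if (is.null(n) == is.null(threshold))
    stop("supply exactly one of 'n' or 'threshold'", call. = FALSE)
  if (!is.null(n)) {
    stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
    if (n > length(result$ranking))
      stop("'n' exceeds the number of isolates in the panel", call. = FALSE)
    result$ranking[seq_len(n)]
  } else {
    keep <- result$scores[result$ranking] >= threshold
    result$ranking[keep]
  }
}

#' Read an assay panel from CSV
#'
#' Expects a delimited table whose first column holds isolate ids and whose
#' remaining columns are assay variables; weights and polarity may be
#' supplied programmatically or via a side-car JSON/YAML read by the caller.
#'
#' @param path CSV file path.
#' @param weights,polarity passed to [assay_panel()].
#' @return An [assay_panel()].
#' @export
read_assay_panel <- function(path, weights = NULL, polarity = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("panel file needs an id column plus assay columns", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  assay_panel(m, isolate_ids = as.character(df[[1L]]),
              variables = colnames(df)[-1L],
              weights = weights, polarity = polarity)
}

#' Write scoring results to CSV
#'
#' Emits the normalized matrix joined with the standard scores and ranks,
#' one row per isolate in input order.
#'
#' @param result a `score_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_result <- function(result, path) {
  stopifnot(inherits(result, "score_result"))
  rank_of <- match(rownames(result$normalized), result$ranking)
  df <- data.frame(isolate_id = rownames(result$normalized),
                   result$normalized,
                   SS = unname(result$scores),
                   rank = rank_of,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
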