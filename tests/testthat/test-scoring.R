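test_that("min-max normalization rescales each assay to [0, 1]", {
  pan <- assay_panel(cbind(SR = c(2, 5, 8), UAG = c(1, 2, 4)))
  norm <- normalize_scores(pan)
  expect_equal(unname(norm[, "SR"]), c(0, 0.5, 1))
  expect_equal(unname(norm[, "UAG"]), c(0, 1 / 3, 1))

  # each non-constant column touches both 0 and 1
  set.seed(7)
  pan2 <- assay_panel(matrix(runif(60), 10, 6))
  n2 <- normalize_scores(pan2)
  expect_true(all(n2 >= 0 & n2 <= 1))
  expect_equal(unname(apply(n2, 2, min)), rep(0, 6))
  expect_equal(unname(apply(n2, 2, max)), rep(1, 6))
})

test_that("constant assays normalize to zero with a warning", {
  pan <- assay_panel(cbind(SR = c(7, 7, 7), UAG = c(0, 1, 2)))
  expect_warning(norm <- normalize_scores(pan), "constant")
  expect_equal(unname(norm[, "SR"]), c(0, 0, 0))
})

test_that("normalization is idempotent and reflects negative polarity", {
  pan <- assay_panel(cbind(x = c(0, 0.25, 1)))
  once <- normalize_scores(pan)
  again <- normalize_scores(assay_panel(once))
  expect_equal(once, again)

  neg <- assay_panel(cbind(x = c(2, 5, 8)), polarity = -1)
  expect_equal(unname(normalize_scores(neg)[, 1]), c(1, 0.5, 0))
})

test_that("standard score is the weighted sum of normalized values", {
  # two variables, equal weights: normalized (1, 0.5) -> SS 0.75
  raw <- cbind(v1 = c(0, 1, 2), v2 = c(0, 1, 2))
  # isolate 2 has normalized (0.5, 0.5); isolate 3 (1, 1)
  res <- standard_score(assay_panel(raw))
  expect_equal(unname(res$scores), c(0, 0.5, 1))

  # isolate with normalized values (1, 0.5) under equal weights scores 0.75
  pan4 <- assay_panel(cbind(a = c(0, 1, 0.5), b = c(0, 0.5, 1)))
  s4 <- standard_score(pan4)
  expect_equal(unname(s4$scores[2]), 0.5 * 1 + 0.5 * 0.5)
})

test_that("all-maxima and all-minima isolates score 1 and 0", {
  set.seed(11)
  raw <- matrix(runif(5 * 9, 1, 2), 5, 9)
  raw[1, ] <- 2.5  # attains every column maximum
  raw[2, ] <- 0.5  # attains every column minimum
  res <- standard_score(assay_panel(raw))
  expect_equal(unname(res$scores[1]), 1)
  expect_equal(unname(res$scores[2]), 0)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  # SS = 1 only for the all-maxima isolate
  expect_equal(unname(which(res$scores == 1)), 1L)
})

test_that("standard score is invariant to affine rescaling of raw columns", {
  set.seed(3)
  raw <- matrix(runif(8 * 4), 8, 4)
  base <- standard_score(assay_panel(raw))$scores
  scaled <- raw
  scaled[, 1] <- 100 * raw[, 1] - 7
  scaled[, 3] <- 0.02 * raw[, 3] + 1000
  expect_equal(unname(standard_score(assay_panel(scaled))$scores),
               unname(base), tolerance = 1e-9)
})

test_that("raising one raw value never lowers that isolate's score", {
  set.seed(5)
  raw <- matrix(runif(6 * 3), 6, 3)
  base <- standard_score(assay_panel(raw))$scores
  for (j in 1:3) {
    i <- which(raw[, j] != max(raw[, j]))[1L]
    bumped <- raw
    bumped[i, j] <- bumped[i, j] + 0.5 * (max(raw[, j]) - bumped[i, j])
    new <- standard_score(assay_panel(bumped))$scores
    expect_gte(new[i], base[i] - 1e-12)
  }
})

test_that("standard score matches a brute-force spreadsheet recomputation", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(2:5, 1); p <- sample(2:3, 1)
    raw <- matrix(runif(n * p, -3, 9), n, p)
    w <- runif(p); w <- w / sum(w)
    got <- standard_score(assay_panel(raw, weights = w))$scores
    expect_equal(unname(got), brute_force_ss(raw, w), tolerance = 1e-12)
  }
})

test_that("selection by rank and by threshold behaves as documented", {
  raw <- cbind(x = c(0.9, 0.3))
  res <- standard_score(assay_panel(raw, isolate_ids = c("A", "B")))
  expect_equal(select_top(res, n = 1), "A")
  expect_equal(select_top(res, n = 2), c("A", "B"))
  expect_error(select_top(res, n = 3), "exceeds")
  expect_error(select_top(res), "exactly one")

  # threshold keeps every isolate at or above the cut, ties intact
  res2 <- structure(list(scores = c(I1 = 0.996, I2 = 0.996, I3 = 0.775),
                         ranking = c("I1", "I2", "I3")),
                    class = "score_result")
  expect_equal(select_top(res2, threshold = 0.95), c("I1", "I2"))
})

test_that("ranking ties break stably by input order", {
  raw <- cbind(x = c(1, 3, 3, 0))
  res <- standard_score(assay_panel(raw, isolate_ids = c("w", "x", "y", "z")))
  expect_equal(res$ranking, c("x", "y", "w", "z"))
})

test_that("panel construction rejects malformed input", {
  expect_error(assay_panel(matrix(numeric(0), 0, 0)), "empty")
  expect_error(assay_panel(cbind(x = c(1, NA)), isolate_ids = c("A", "B")),
               "isolate 'B'.*'x'")
  expect_error(assay_panel(cbind(x = 1:3), weights = -1), "nonnegative")
})

test_that("panels round-trip through CSV with scores attached", {
  pan <- simulate_assay_panel(10, 2, seed = 4)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(isolate_id = pan$isolate_ids, pan$raw,
                              check.names = FALSE), f, row.names = FALSE)
  back <- read_assay_panel(f)
  expect_equal(back$raw, pan$raw, tolerance = 1e-12)
  out <- tempfile(fileext = ".csv")
  write_score_result(standard_score(back), out)
  scored <- utils::read.csv(out, check.names = FALSE)
  expect_true(all(c("isolate_id", "SS", "rank") %in% names(scored)))
  expect_equal(nrow(scored), 10L)
})
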