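test_that("ureolysis fit recovers generating parameters from noiseless data", {
  p <- ureolysis_params(0.03, 19.55)
  fit <- fit_ureolysis(make_urea_traj(p))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$k_urea, 0.03), 1e-6)
  expect_lt(rel_err(fit$params$c_urea0, 19.55), 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("ureolysis fit handles flat, degenerate and invalid trajectories", {
  flat <- trajectory("ref", "urea_gL", hours_schedule,
                     rep(19.878, length(hours_schedule)))
  fit <- fit_ureolysis(flat)
  expect_identical(fit$params$k_urea, 0)
  expect_equal(fit$params$c_urea0, 19.878)
  expect_true(fit$converged)
  expect_equal(fit$r2, 1)  # zero residuals against zero variance

  expect_error(fit_ureolysis(trajectory("x", "urea_gL", 0, 19)), "3 distinct")
  expect_error(fit_ureolysis(make_sigmoid_traj(sigmoid_params(7, 9, 3, 1))),
               "urea_gL")

  rising <- trajectory("x", "urea_gL", c(0, 6, 12, 24), c(1, 2, 3, 4))
  bad <- fit_ureolysis(rising)
  expect_false(bad$converged)
  expect_match(bad$message, "nondecreasing")

  zeros <- trajectory("x", "urea_gL", c(0, 6, 12), c(0, 0, 0))
  z <- fit_ureolysis(zeros)
  expect_false(z$converged)
})

test_that("cell density rescales the reported ureolysis rate", {
  # k and c_x enter only as a product: halving c_x doubles the reported k
  p <- ureolysis_params(0.05, 19.9, c_x = 1)
  tr <- make_urea_traj(p)
  f2 <- fit_ureolysis(tr, c_x = 2)
  expect_lt(rel_err(f2$params$k_urea, 0.025), 1e-6)
  expect_equal(f2$params$c_x, 2)
})

test_that("one-parameter exponential fit agrees with a dense grid search", {
  # independent oracle: exhaustive scan of k over [0, 10] with c0 fixed
  p <- ureolysis_params(0.61, 18.2)
  tr <- make_urea_traj(p, times = c(0, 1, 2, 4, 8, 16))
  fit <- fit_ureolysis(tr, fix_c0 = TRUE)
  kk <- seq(0, 10, length.out = 1e5)
  ss <- vapply(kk, function(k) sum((tr$values - 18.2 * exp(-k * tr$times))^2),
               numeric(1))
  k_grid <- kk[which.min(ss)]
  expect_lt(abs(fit$params$k_urea - k_grid), 10 / 1e5)
})

test_that("sigmoid fit recovers generating parameters from noiseless data", {
  cases <- list(
    list(p = sigmoid_params(7.19, 9.15, 3.07, 1.37), var = "pH",
         times = hours_schedule, unit = "hours"),
    list(p = sigmoid_params(5.03, 11.66, 32.15, 0.8), var = "log_cells",
         times = hours_schedule, unit = "hours"),
    list(p = sigmoid_params(0.001, 0.51, 2.82, 6.00), var = "precipitate_g",
         times = as.numeric(days_schedule), unit = "days"))
  for (cs in cases) {
    tr <- make_sigmoid_traj(cs$p, variable = cs$var, times = cs$times,
                            unit = cs$unit)
    fit <- fit_sigmoid(tr)
    expect_true(fit$converged)
    for (nm in c("a", "d", "c", "b"))
      expect_lt(rel_err(fit$params[[nm]], cs$p[[nm]]), 1e-4)
  }
})

test_that("sigmoid fit degenerates gracefully on constant data", {
  flat <- trajectory("x", "pH", hours_schedule, rep(7.31, length(hours_schedule)))
  expect_warning(fit <- fit_sigmoid(flat), "constant")
  expect_equal(fit$params$a, 7.31)
  expect_equal(fit$params$d, 7.31)
  expect_equal(fit$r2, 1)
  expect_error(fit_sigmoid(trajectory("x", "pH", c(0, 1, 2, 3), c(7, 8, 8, 9))),
               "5 distinct")
})

test_that("precipitation fit recovers steep and flat decays", {
  steep <- fit_precipitation(make_ca_traj(precipitation_params(4.84, 1266)))
  expect_true(steep$converged)
  expect_lt(rel_err(steep$params$k_precipitate, 4.84), 1e-6)
  expect_lt(rel_err(steep$params$c_ca0, 1266), 1e-6)

  flat <- fit_precipitation(trajectory("x", "calcium_mgL", days_schedule,
                                       rep(1237.18, 15), time_unit = "days"))
  expect_identical(flat$params$k_precipitate, 0)

  # two-point analytic solution: k = -log(c1/c0) for t1 - t0 = 1
  tr <- trajectory("x", "calcium_mgL", c(0, 1, 2),
                   1200 * exp(-0.7 * c(0, 1, 2)), time_unit = "days")
  f <- fit_precipitation(tr)
  expect_lt(abs(f$params$k_precipitate - 0.6999999999999998), 1e-6)
})

test_that("round-trip recovery holds over random parameter draws", {
  set.seed(101)
  for (i in 1:20) {
    k <- runif(1, 0.005, 0.15)
    c0 <- runif(1, 15, 25)
    f <- fit_ureolysis(make_urea_traj(ureolysis_params(k, c0)))
    expect_lt(rel_err(f$params$k_urea, k), 1e-6)
    expect_lt(rel_err(f$params$c_urea0, c0), 1e-6)
  }
  for (i in 1:15) {
    p <- sigmoid_params(a = runif(1, 6.8, 7.6), d = runif(1, 8, 10),
                        c = runif(1, 2, 30), b = runif(1, 0.6, 8))
    f <- fit_sigmoid(make_sigmoid_traj(p))
    for (nm in c("a", "d", "c", "b"))
      expect_lt(rel_err(f$params[[nm]], p[[nm]]), 1e-4)
  }
  for (i in 1:15) {
    k <- runif(1, 0.02, 5)
    c0 <- runif(1, 1100, 1350)
    f <- fit_precipitation(make_ca_traj(precipitation_params(k, c0)))
    expect_lt(rel_err(f$params$k_precipitate, k), 1e-6)
    expect_lt(rel_err(f$params$c_ca0, c0), 1e-6)
  }
})

test_that("rate estimates are robust to moderate measurement noise", {
  # sigma = 2% of the dynamic range; median relative error under 5%
  p <- ureolysis_params(0.04, 19.99)
  mu <- urea_model(hours_schedule, p)
  sigma <- 0.02 * diff(range(mu))
  set.seed(202)
  errs <- replicate(200, {
    v <- pmax(mu + rnorm(length(mu), 0, sigma), 0)
    f <- fit_ureolysis(trajectory("x", "urea_gL", hours_schedule, v))
    rel_err(f$params$k_urea, 0.04)
  })
  expect_lt(median(errs), 0.05)
})

test_that("fits do not depend on the ordering of input rows", {
  p <- precipitation_params(0.36, 1171.96)
  tr <- make_ca_traj(p)
  df <- data.frame(strain = "x", variable = "calcium_mgL", time = tr$times,
                   time_unit = "days", value = tr$values)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f1, row.names = FALSE)
  set.seed(9); utils::write.csv(df[sample(nrow(df)), ], f2, row.names = FALSE)
  fit1 <- fit_precipitation(read_trajectories(f1)[[1]])
  fit2 <- fit_precipitation(read_trajectories(f2)[[1]])
  expect_equal(fit1$params$k_precipitate, fit2$params$k_precipitate)
  expect_equal(fit1$params$c_ca0, fit2$params$c_ca0)
})

test_that("goodness of fit matches its definition", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r2, 1); expect_equal(g$rmse, 0)

  obs <- c(4, 7, 1, 9)
  g2 <- goodness_of_fit(obs, rep(mean(obs), 4))
  expect_equal(g2$r2, 0)

  g3 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g3$r2, 0.5)
  expect_equal(g3$rmse, sqrt(1 / 3))
  expect_equal(g3$residuals, c(0, 0, -1))

  expect_warning(g4 <- goodness_of_fit(c(2, 2, 2), c(2, 2, 3)), "undefined")
  expect_true(is.nan(g4$r2))
})

test_that("training r2 of a converged fit never falls below zero", {
  set.seed(33)
  for (i in 1:10) {
    v <- pmax(urea_model(hours_schedule, ureolysis_params(0.05, 20)) +
                rnorm(12, 0, 2), 0)
    f <- fit_ureolysis(trajectory("x", "urea_gL", hours_schedule, v))
    if (f$converged) expect_gte(f$r2, 0)
  }
})

test_that("lack-of-fit test is calm under the null and alarmed under bias", {
  tt <- rep(c(0, 2, 4, 8, 16, 32), each = 3)
  p <- ureolysis_params(0.08, 20)
  # replicated data from the fitted model family + iid noise: p should be
  # comfortably above 0.05 at this fixed seed
  set.seed(55)
  v <- pmax(urea_model(tt, p) + rnorm(length(tt), 0, 0.25), 0)
  tr <- trajectory("x", "urea_gL", tt, v, replicates = rep(1:3, times = 6))
  fit <- fit_ureolysis(tr)
  lof <- lack_of_fit_test(tr, fit)
  expect_gt(lof$p_value, 0.05)

  # strong systematic bump a monotone decay cannot follow
  v2 <- v + rep(c(0, 0, 6, 6, 0, 0), each = 3)
  tr2 <- trajectory("x", "urea_gL", tt, v2, replicates = rep(1:3, times = 6))
  fit2 <- fit_ureolysis(tr2)
  lof2 <- lack_of_fit_test(tr2, fit2)
  expect_lt(lof2$p_value, 0.01)

  # no replication: explicit skip
  tr3 <- make_urea_traj(p)
  expect_message(lof3 <- lack_of_fit_test(tr3, fit_ureolysis(tr3)), "skipped")
  expect_true(is.na(lof3$p_value))
})

test_that("lack-of-fit p-values are roughly uniform under the null", {
  tt <- rep(c(0, 2, 4, 8, 16, 32), each = 2)
  p <- ureolysis_params(0.08, 20)
  set.seed(77)
  pv <- replicate(60, {
    v <- urea_model(tt, p) + rnorm(length(tt), 0, 0.2)
    tr <- trajectory("x", "urea_gL", tt, pmax(v, 0))
    lack_of_fit_test(tr, fit_ureolysis(tr))$p_value
  })
  # a uniform sample of 60 should not concentrate in either tail
  expect_gt(mean(pv > 0.05), 0.8)
  expect_gt(min(pv), 0)
  expect_true(mean(pv) > 0.3 && mean(pv) < 0.7)
})
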