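test_that("baseline cumulative hazard reduces to Nelson-Aalen at beta = 0", {
  # n distinct event times, no censoring: first step is 1/n
  time <- c(1, 2, 3, 4, 5)
  d <- survival_dataset(time, rep(1, 5), matrix(0, 5, 1))
  ch <- ah_cumhaz(d, 0)
  expect_equal(evaluate_cumhaz(ch, 1), 1 / 5)
  na <- cumsum(1 / (5:1))
  expect_equal(evaluate_cumhaz(ch, time), na, tolerance = 1e-12)
  # between events the curve is flat when beta = 0
  expect_equal(evaluate_cumhaz(ch, 2.5), na[2])
  # no events at all: identically zero
  d0 <- survival_dataset(time, rep(0, 5), matrix(0, 5, 1))
  ch0 <- ah_cumhaz(d0, 0)
  expect_equal(evaluate_cumhaz(ch0, c(0.5, 3, 5)), c(0, 0, 0))
})

test_that("cumulative hazard drift matches the risk-set mean linear predictor", {
  d <- random_dataset(12, 3, seed = 71)
  beta <- c(0.5, -0.2, 0.1)
  ch <- ah_cumhaz(d, beta)
  lp <- drop(d$covariates %*% beta)
  ut <- sort(unique(d$time))
  # numerical derivative strictly inside an inter-event interval
  for (k in c(2L, 5L)) {
    t1 <- ut[k - 1] + 0.2 * (ut[k] - ut[k - 1])
    t2 <- ut[k - 1] + 0.8 * (ut[k] - ut[k - 1])
    deriv <- (evaluate_cumhaz(ch, t2) - evaluate_cumhaz(ch, t1)) / (t2 - t1)
    at_risk <- d$time >= ut[k]
    expect_equal(deriv, -mean(lp[at_risk]), tolerance = 1e-8)
  }
  # beyond the last observed time: flat with a warning
  expect_warning(v <- evaluate_cumhaz(ch, max(d$time) + 1), "flat")
  expect_equal(v, evaluate_cumhaz(ch, max(d$time)))
})

test_that("predicted survival is 1 at t = 0, in [0,1], and nonincreasing", {
  d <- random_dataset(30, 4, seed = 72)
  beta <- rnorm(4, sd = 0.3)
  ch <- ah_cumhaz(d, beta)
  times <- c(1e-12, sort(runif(8, 0.1, max(d$time))))
  S <- predict_survival(beta, ch, d$covariates, times)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(abs(S[, 1] - 1) < 1e-9))
  expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-12))))
  # beta = 0 gives the baseline survival for every subject
  ch0 <- ah_cumhaz(d, rep(0, 4))
  S0 <- predict_survival(rep(0, 4), ch0, d$covariates[1, ], times)
  expect_equal(S0, exp(-evaluate_cumhaz(ch0, times)), tolerance = 1e-12)
})

test_that("predicted survival matches the closed form under the generator", {
  sim <- ah_simulate(ah_sim_config(n = 2000, p = 4, n_true = 2, rho = 0,
                                   seed = 73, clinical = FALSE,
                                   target_events = 2000))
  d <- sim$data
  bt <- sim$truth$beta_true
  ch <- ah_cumhaz(d, bt)
  times <- seq(0.1, 0.8, by = 0.1)
  # central covariate vector: hazard is lambda0 + beta' z
  z <- rep(0.3, 4)
  h <- sim$truth$lambda0 + sum(bt * z)
  S <- predict_survival(bt, ch, z, times)
  expect_lt(max(abs(S - exp(-h * times))), 0.05)
})

test_that("time-dependent AUC matches the exhaustive pairwise oracle", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  status <- rep(1, 8)
  set.seed(74)
  marker <- c(3.1, 2.7, 2.7, 1.9, 2.0, 1.2, 0.5, 0.8)
  d <- survival_dataset(time, status, matrix(0, 8, 1))
  times <- time[time < 8]
  curve <- auc_t(marker, d, times)
  oracle <- vapply(times, function(t) pairwise_auc(marker, time, status, t),
                   numeric(1))
  expect_equal(curve$values, oracle, tolerance = 1e-12)
})

test_that("AUC is 1 for a perfectly ordering marker and 0.5 for a constant", {
  time <- c(1, 2, 3, 4, 5, 6)
  d <- survival_dataset(time, rep(1, 6), matrix(0, 6, 1))
  # earlier event = higher risk score
  perfect <- auc_t(-time, d)
  expect_true(all(perfect$values == 1))
  flat <- auc_t(rep(2, 6), d)
  expect_true(all(flat$values == 0.5))
  # invariance under strictly increasing marker transforms
  d2 <- random_dataset(25, 1, seed = 75)
  m <- rnorm(25)
  c1 <- auc_t(m, d2)
  c2 <- auc_t(exp(3 * m), d2)
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
  expect_true(all(c1$values >= 0 & c1$values <= 1))
})

test_that("median_auc follows the stated conventions", {
  expect_equal(median_auc(eval_curve(1:3, c(0.8, 0.8, 0.8))), 0.8)
  expect_equal(median_auc(eval_curve(1:3, c(0.6, 0.7, 0.9))), 0.7)
  expect_equal(median_auc(eval_curve(1:2, c(0.6, 0.8))), 0.7)
  expect_error(median_auc(eval_curve(numeric(0), numeric(0))), "empty")
})

test_that("brier curve is exact on uncensored data", {
  time <- c(1, 2, 3, 4)
  status <- rep(1, 4)
  d <- survival_dataset(time, status, matrix(0, 4, 1))
  times <- c(1.5, 2.5, 3.5)
  # perfect oracle predictions: S_i(t) = 1 - state_i(t)
  state <- outer(time, times, function(x, t) as.numeric(x <= t))
  expect_equal(brier_curve(1 - state, d, times)$values, c(0, 0, 0))
  # constant 0.5 prediction scores 0.25 everywhere
  expect_equal(brier_curve(matrix(0.5, 4, 3), d, times)$values,
               rep(0.25, 3))
  # hand-computed mean squared error for an arbitrary prediction
  set.seed(76)
  S <- matrix(runif(12), 4, 3)
  got <- brier_curve(S, d, times)$values
  want <- colMeans((state - (1 - S))^2)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(brier_curve(matrix(2, 4, 3), d, times), "\\[0, 1\\]")
})

test_that("brier curve vanishes as t -> 0 when predictions start at 1", {
  d <- random_dataset(30, 1, seed = 77)
  times <- c(1e-9, 0.5)
  S <- matrix(1, 30, 2)
  S[, 2] <- 0.7
  vals <- brier_curve(S, d, times)$values
  expect_lt(vals[1], 1e-12)
})

test_that(".632+ weight algebra holds", {
  expect_equal(w632plus(0), 0.632)
  expect_equal(w632plus(1), 1)
  expect_equal(w632plus(0.5), 0.632 / (1 - 0.368 * 0.5))
  # R clipped into [0, 1]
  expect_equal(w632plus(-3), 0.632)
  expect_equal(w632plus(7), 1)
  # oob = app everywhere collapses to the apparent error
  app <- c(0.1, 0.2)
  R <- ahpen:::relative_overfit(app, app, c(0.25, 0.25))
  w <- w632plus(R)
  expect_equal((1 - w) * app + w * pmin(app, c(0.25, 0.25)), app)
})

test_that(".632+ curve lies between the apparent and max(oob, noinf) curves", {
  sim <- ah_simulate(ah_sim_config(n = 60, p = 5, n_true = 2, seed = 78,
                                   clinical = FALSE, target_events = 40))
  d <- sim$data
  proc <- function(train) {
    ss <- ah_suffstats(train)
    beta <- ah_lsfit(ss)
    ch <- ah_cumhaz(train, beta)
    function(newdata, times) {
      predict_survival(as.numeric(beta), ch, newdata$covariates, times)
    }
  }
  times <- ahpen:::event_time_grid(d, 15L)
  e <- error632plus(d, proc, times, B = 25, seed = 4)
  # the estimate is a convex combination of the apparent error and
  # min(oob, no-information), so it lies pointwise between them
  other <- pmin(e$oob$values, e$noinf$values)
  expect_true(all(e$curve$values >= pmin(e$apparent$values, other) - 1e-12))
  expect_true(all(e$curve$values <= pmax(e$apparent$values, other) + 1e-12))
  # and reproduces the weighting formula exactly
  expect_equal(e$curve$values,
               (1 - e$w) * e$apparent$values + e$w * other,
               tolerance = 1e-12)
  expect_true(all(e$w >= 0.632 & e$w <= 1))
  # deterministic under the same seed
  e2 <- error632plus(d, proc, times, B = 25, seed = 4)
  expect_identical(e$curve$values, e2$curve$values)
  # with-replacement variant runs and differs in its resamples
  e3 <- error632plus(d, proc, times, B = 5, seed = 4, replace = TRUE)
  expect_s3_class(e3$curve, "eval_curve")
})

test_that("stability table aggregates frequency, mean and SE correctly", {
  # deterministic strong signal: one feature always selected with a
  # stable coefficient, others never
  sim <- ah_simulate(ah_sim_config(n = 120, p = 6, n_true = 1, rho = 0,
                                   beta_true = c(2, 0, 0, 0, 0, 0),
                                   seed = 79, clinical = FALSE,
                                   target_events = 90))
  tab <- stability_replicates(sim$data, "lasso", R = 8, seed = 6,
                              nfolds = 4)
  expect_s3_class(tab, "stability_table")
  expect_equal(attr(tab, "R_effective"), 8L)
  expect_true("g0001" %in% tab$feature)
  row <- tab[tab$feature == "g0001", ]
  expect_equal(row$frequency, 8L)
  # never-selected features are absent rather than zero-frequency
  expect_true(all(tab$frequency > 0))
  expect_true(all(tab$frequency <= 8L))
  # SE definition: SD of selected coefficients / sqrt(frequency)
  expect_true(is.finite(row$se_coef))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_stability_table(tab, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(back$frequency, tab$frequency)
})

test_that("stability replicates recover a strong true support", {
  ok <- 0L
  n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    sim <- ah_simulate(ah_sim_config(n = 150, p = 20, n_true = 3,
                                     rho = 0.3, beta_range = c(0.8, 1),
                                     seed = 800 + s, clinical = FALSE,
                                     target_events = 110))
    tab <- stability_replicates(sim$data, "lasso", R = 10, seed = 800 + s,
                                nfolds = 5)
    truth <- names(which(sim$truth$beta_true != 0))
    freq <- tab$frequency[match(truth, tab$feature)]
    freq[is.na(freq)] <- 0L
    if (all(freq >= 8)) ok <- ok + 1L
  }
  expect_gte(ok, n_seeds - 1L)
})

test_that("a fitted risk marker beats noise by a wide AUC margin", {
  sim <- ah_simulate(ah_sim_config(n = 1000, p = 10, n_true = 4, rho = 0,
                                   beta_range = c(0.8, 1), seed = 81,
                                   clinical = FALSE, target_events = 1000))
  d <- sim$data
  truth_marker <- drop(d$covariates %*% sim$truth$beta_true)
  set.seed(81)
  noise_marker <- rnorm(d$n)
  m1 <- median_auc(auc_t(truth_marker, d))
  m2 <- median_auc(auc_t(noise_marker, d))
  expect_gt(m1 - m2, 0.2)
})

test_that("eval_curve validates its inputs", {
  expect_error(eval_curve(c(1, 2), 1), "equal length")
  expect_error(eval_curve(c(2, 1), c(0.1, 0.2)), "increasing")
})
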