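test_that("degenerate datasets give zero sufficient statistics", {
  # single subject: risk-set mean equals its own covariates
  d1 <- survival_dataset(2, 1, matrix(c(3.2, -1), 1, 2))
  ss1 <- ah_suffstats(d1)
  expect_equal(unname(ss1$b), c(0, 0))
  expect_equal(unname(ss1$V), matrix(0, 2, 2))

  # identical covariate rows: centering wipes everything
  d2 <- survival_dataset(c(1, 2), c(1, 1),
                         matrix(c(1.5, 1.5, -2, -2), 2, 2))
  ss2 <- ah_suffstats(d2)
  expect_equal(unname(ss2$b), c(0, 0))
  expect_equal(max(abs(ss2$V)), 0)

  # no events: b = 0 with a warning
  d3 <- survival_dataset(c(1, 2), c(0, 0), matrix(rnorm(4), 2, 2))
  expect_warning(ss3 <- ah_suffstats(d3), "no events")
  expect_equal(unname(ss3$b), c(0, 0))
})

test_that("suffstats match the fine-grid Riemann oracle on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1)
    p <- sample(1:3, 1)
    time <- round(runif(n, 0.3, 4), 2)
    status <- rbinom(n, 1, 0.7)
    Z <- matrix(rnorm(n * p), n, p)
    d <- survival_dataset(time, status, Z)
    ss <- ah_suffstats(d)
    or <- riemann_suffstats(time, status, Z)
    sc <- max(abs(or$V), 1e-8)
    expect_lt(max(abs(unname(ss$V) - or$V)) / sc, 1e-3)
    expect_lt(max(abs(unname(ss$b) - or$b)) / max(abs(or$b), 1e-8), 1e-3)
  }
})

test_that("V is symmetric PSD and invariant to covariate location shifts", {
  d <- random_dataset(12, 3, seed = 7)
  ss <- ah_suffstats(d)
  expect_lt(max(abs(ss$V - t(ss$V))), 1e-10)
  ev <- eigen(ss$V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(ss$V)))
  # shifting every subject's covariates by a constant changes nothing
  d2 <- survival_dataset(d$time, d$status,
                         sweep(d$covariates, 2L, c(5, -3, 100), "+"))
  ss2 <- ah_suffstats(d2)
  expect_equal(ss2$b, ss$b, tolerance = 1e-10)
  expect_equal(ss2$V, ss$V, tolerance = 1e-10)
})

test_that("scaling all times by c scales V by c and leaves b unchanged", {
  d <- random_dataset(10, 2, seed = 21)
  ss <- ah_suffstats(d)
  cc <- 3.7
  d2 <- survival_dataset(d$time * cc, d$status, d$covariates)
  ss2 <- ah_suffstats(d2)
  expect_equal(ss2$b, ss$b, tolerance = 1e-12)
  expect_equal(ss2$V, cc * ss$V, tolerance = 1e-10)
})

test_that("loss has its closed forms and matches independent arithmetic", {
  ss <- fake_suffstats(b = c(1, -2), V = diag(2))
  expect_identical(ah_loss(c(0, 0), ss), 0)
  # V = I, b = 0: loss is half the squared norm
  ss0 <- fake_suffstats(b = c(0, 0, 0), V = diag(3))
  beta <- c(1, 2, -2)
  expect_equal(ah_loss(beta, ss0), 0.5 * sum(beta^2))
  # random PSD case vs direct independently coded evaluation
  for (seed in 1:5) {
    set.seed(seed)
    V <- random_psd(5, seed)
    b <- rnorm(5)
    beta <- rnorm(5)
    ssr <- fake_suffstats(b, V)
    direct <- 0.5 * drop(t(beta) %*% V %*% beta) - drop(t(b) %*% beta)
    expect_equal(ah_loss(beta, ssr), direct, tolerance = 1e-12)
  }
  expect_error(ah_loss(c(1, 2, 3), ss), "p = 2")
})

test_that("unpenalized fit solves the pseudo-score equation", {
  expect_equal(as.numeric(ah_lsfit(fake_suffstats(c(0, 0), diag(2) * 3))),
               c(0, 0))
  expect_equal(as.numeric(ah_lsfit(fake_suffstats(c(2, -4), 2 * diag(2)))),
               c(1, -2))
  set.seed(9)
  V <- random_psd(4, 9, ridge = 0.5)
  b <- rnorm(4)
  beta <- ah_lsfit(fake_suffstats(b, V))
  expect_lt(sqrt(sum((V %*% beta - b)^2)), 1e-10)
  expect_false(attr(beta, "rank_deficient"))
  # score vanishes at the fit
  expect_lt(max(abs(ah_score(as.numeric(beta), fake_suffstats(b, V)))), 1e-10)
})

test_that("singular V yields the flagged minimum-norm solution", {
  u <- c(1, 2) / sqrt(5)
  V <- outer(u, u)          # rank 1
  b <- u * 3                # in range(V)
  beta <- ah_lsfit(fake_suffstats(b, V))
  expect_true(attr(beta, "rank_deficient"))
  expect_equal(attr(beta, "rank"), 1L)
  expect_lt(max(abs(V %*% beta - b)), 1e-10)
  # minimum norm: solution is along u
  expect_equal(unname(as.numeric(beta)), 3 * u, tolerance = 1e-10)
})

test_that("low-memory representation reproduces the dense results", {
  d <- random_dataset(25, 8, seed = 13)
  dense <- ah_suffstats(d)
  lm <- ah_suffstats(d, lowmem = TRUE)
  expect_null(lm$V)
  expect_equal(lm$b, dense$b, tolerance = 1e-12)
  expect_equal(lm$Vdiag, unname(dense$Vdiag), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in c(1L, 4L, 8L)) {
    expect_equal(unname(ahpen:::ah_v_column(lm, j)), unname(dense$V[, j]),
                 tolerance = 1e-10)
  }
  beta <- rnorm(8)
  expect_equal(ahpen:::ah_v_times(lm, beta),
               unname(drop(dense$V %*% beta)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ah_loss(beta, lm), ah_loss(beta, dense), tolerance = 1e-10)
})

test_that("tau beyond the last observed time truncates with a warning", {
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 0), matrix(rnorm(6), 3, 2),
                        tau = 10)
  expect_warning(ss <- ah_suffstats(d), "truncated")
  d2 <- survival_dataset(c(1, 2, 3), c(1, 1, 0), d$covariates, tau = 3)
  ss2 <- ah_suffstats(d2)
  expect_equal(ss$V, ss2$V, tolerance = 1e-12)
  expect_equal(ss$b, ss2$b, tolerance = 1e-12)
})

test_that("events at exactly tau are counted in b", {
  Z <- matrix(c(1, -1, 0.5, 2, 0, 1), 3, 2)
  d_full <- survival_dataset(c(1, 3, 3), c(0, 1, 1), Z, tau = 3)
  b_full <- ah_suffstats(d_full)$b
  d_cut <- survival_dataset(c(1, 3, 3), c(0, 1, 1), Z, tau = 2.5)
  b_cut <- ah_suffstats(d_cut)$b
  # both events occur exactly at tau = 3; risk set there is {2, 3}
  zbar <- colMeans(Z[2:3, ])
  expect_equal(unname(b_full),
               unname((Z[2, ] - zbar) + (Z[3, ] - zbar)) / 3,
               tolerance = 1e-12)
  # truncating below the event time removes them entirely
  expect_equal(unname(b_cut), c(0, 0))
})
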