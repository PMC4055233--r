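test_that("lambda = 0 coordinate descent matches the direct linear solve", {
  set.seed(10)
  V <- random_psd(10, 10, ridge = 0.3)
  b <- rnorm(10)
  ss <- fake_suffstats(b, V)
  direct <- solve(V, b)
  for (kind in c("lasso", "scad", "sica")) {
    f <- ah_fit(ss, penalty_spec(kind, 0, a = if (kind == "scad") 3.7 else 1),
                tol = 1e-10)
    expect_lt(max(abs(f$beta - direct)), 1e-8)
  }
})

test_that("identity V makes the lasso fit exact soft thresholding", {
  b <- c(2, -0.3, 0.8, -1.5, 0.05)
  ss <- fake_suffstats(b, diag(5))
  lam <- 0.5
  f <- ah_fit(ss, penalty_spec("lasso", lam))
  expect_identical(unname(f$beta), sign(b) * pmax(abs(b) - lam, 0))
  expect_lte(f$sweeps, 2L)   # separable: one working sweep + confirmation
})

test_that("identity V nonconvex fits match the univariate grid oracle", {
  set.seed(11)
  b <- runif(6, -2, 2)
  ss <- fake_suffstats(b, diag(6))
  for (kind in c("scad", "sica")) {
    a <- if (kind == "scad") 3.7 else 0.8
    spec <- penalty_spec(kind, 0.4, a = a)
    f <- ah_fit(ss, spec)
    for (j in 1:6) {
      obj_hat <- uni_objective(spec, b[j], 1, f$beta[j])
      obj_star <- uni_objective(spec, b[j], 1, grid_uni_min(spec, b[j], 1))
      expect_lte(obj_hat, obj_star + 1e-6)
    }
  }
})

test_that("scad on correlated V attains the multi-start oracle objective", {
  set.seed(12)
  V <- random_psd(4, 12, ridge = 0.05)
  b <- rnorm(4)
  ss <- fake_suffstats(b, V)
  spec <- penalty_spec("scad", 0.3, a = 3.7)
  f <- ah_fit(ss, spec, tol = 1e-9)
  qval <- function(beta) {
    0.5 * drop(t(beta) %*% V %*% beta) - sum(b * beta) +
      sum(penalty_value(spec, abs(beta)))
  }
  expect_equal(f$objective, qval(f$beta), tolerance = 1e-10)
  # multi-start oracle: random inits plus all sign-pattern warm starts
  best <- Inf
  starts <- list()
  for (r in 1:50) starts[[r]] <- rnorm(4, sd = 2)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 4)))
  base <- abs(solve(V, b))
  for (r in seq_len(nrow(signs))) starts[[50 + r]] <- signs[r, ] * base
  for (st in starts) {
    g <- ah_fit(ss, spec, beta_init = st, tol = 1e-9)
    best <- min(best, g$objective)
  }
  expect_lte(f$objective, best + 1e-6)
})

test_that("objective trace is nonincreasing and never above Q(0) = 0", {
  for (seed in 1:6) {
    d <- random_dataset(20, 6, seed = seed)
    ss <- ah_suffstats(d)
    for (kind in c("lasso", "scad", "sica")) {
      f <- ah_fit(ss, penalty_spec(kind, 0.05,
                                   a = if (kind == "scad") 3.7 else 1))
      expect_true(all(diff(f$objective_trace) <= 1e-12))
      expect_lte(f$objective, 0)
      expect_equal(f$n_nonzero, sum(f$beta != 0))
    }
  }
})

test_that("coordinates with zero V_jj stay frozen at zero", {
  V <- diag(c(1, 0, 2))
  b <- c(1, 5, -1)   # huge score on the dead coordinate
  f <- ah_fit(fake_suffstats(b, V), penalty_spec("lasso", 0.1))
  expect_identical(unname(f$beta[2]), 0)
})

test_that("active-set acceleration agrees with plain cyclic descent", {
  d <- random_dataset(40, 12, seed = 31)
  ss <- ah_suffstats(d)
  for (kind in c("lasso", "scad")) {
    spec <- penalty_spec(kind, 0.03, a = 3.7)
    f1 <- ah_fit(ss, spec, active_set = TRUE, tol = 1e-8)
    f2 <- ah_fit(ss, spec, active_set = FALSE, tol = 1e-8)
    expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  }
})

test_that("low-memory fits equal dense fits", {
  d <- random_dataset(30, 10, seed = 17)
  dense <- ah_suffstats(d)
  lm <- ah_suffstats(d, lowmem = TRUE)
  for (kind in c("lasso", "sica")) {
    spec <- penalty_spec(kind, 0.04, a = 1)
    f_d <- ah_fit(dense, spec, active_set = FALSE, tol = 1e-12)
    f_l <- ah_fit(lm, spec, tol = 1e-12)
    expect_equal(f_l$beta, f_d$beta, tolerance = 1e-10)
  }
})

test_that("the path starts empty at lambda_max and warm starts match cold", {
  d <- random_dataset(60, 8, seed = 5, censor_frac = 0.2)
  ss <- ah_suffstats(d)
  fits <- ah_path(ss, "lasso")
  lam <- attr(fits, "lambda")
  expect_equal(lam[1], max(abs(ss$b)))
  expect_equal(fits[[1]]$n_nonzero, 0L)
  # lasso: warm-started solutions equal cold starts
  for (k in c(5L, 20L, 45L)) {
    cold <- ah_fit(ss, penalty_spec("lasso", lam[k]), tol = 1e-9)
    expect_equal(fits[[k]]$beta, cold$beta, tolerance = 1e-5)
  }
  # nonconvex: warm-started objective never worse than cold start
  for (kind in c("scad", "sica")) {
    pf <- ah_path(ss, kind, a = if (kind == "scad") 3.7 else 1)
    for (k in c(10L, 30L, 50L)) {
      cold <- ah_fit(ss, penalty_spec(kind, lam[k],
                                      a = if (kind == "scad") 3.7 else 1))
      expect_lte(pf[[k]]$objective, cold$objective + 1e-8)
    }
  }
  expect_error(ah_path(ss, "lasso", lambda = numeric(0)), "empty")
  expect_error(ah_path(ss, "lasso", lambda = c(0.1, 0.2)), "decreasing")
})

test_that("sparsity is monotone along the lasso path on orthonormal V", {
  set.seed(44)
  b <- rnorm(12)
  ss <- fake_suffstats(b, diag(12))
  fits <- ah_path(ss, "lasso")
  df <- vapply(fits, function(f) f$n_nonzero, integer(1))
  expect_lte(df[1], df[length(df)])
  expect_true(all(diff(df) >= 0))
})

test_that("permuting coordinates permutes the lasso solution", {
  set.seed(50)
  V <- random_psd(7, 50, ridge = 0.2)
  b <- rnorm(7)
  perm <- sample(7)
  f1 <- ah_fit(fake_suffstats(b, V), penalty_spec("lasso", 0.1), tol = 1e-10)
  f2 <- ah_fit(fake_suffstats(b[perm], V[perm, perm]),
               penalty_spec("lasso", 0.1), tol = 1e-10)
  expect_equal(unname(f2$beta), unname(f1$beta[perm]), tolerance = 1e-7)
  # nonconvex: same objective under permutation
  g1 <- ah_fit(fake_suffstats(b, V), penalty_spec("scad", 0.1, a = 3.7))
  g2 <- ah_fit(fake_suffstats(b[perm], V[perm, perm]),
               penalty_spec("scad", 0.1, a = 3.7))
  expect_equal(g2$objective, g1$objective, tolerance = 1e-8)
})
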