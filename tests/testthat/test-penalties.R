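test_that("penalty_spec validates its parameters", {
  expect_error(penalty_spec("scad", 0.5, a = 2), "a > 2")
  expect_error(penalty_spec("sica", 0.5, a = 0), "a > 0")
  expect_error(penalty_spec("lasso", -1), ">= 0")
  expect_equal(penalty_spec("scad", 0.5)$a, 3.7)
  expect_true(is.na(penalty_spec("lasso", 0.5)$a))
})

test_that("rho identities hold at the anchor points", {
  for (kind in c("lasso", "scad", "sica")) {
    spec <- penalty_spec(kind, 0.7, a = if (kind == "scad") 3.7 else 2)
    expect_identical(rho(spec, 0), 0)
    expect_identical(penalty_value(spec, 0), 0)
  }
  # sica: rho(a) = (a+1)/2
  for (a in c(0.5, 1, 3, 10)) {
    expect_equal(rho(penalty_spec("sica", 1, a = a), a), (a + 1) / 2)
  }
  # rho is nondecreasing for all kinds
  th <- seq(0, 5, by = 0.01)
  for (kind in c("lasso", "scad", "sica")) {
    spec <- penalty_spec(kind, 0.6, a = if (kind == "scad") 3.7 else 2)
    expect_true(all(diff(rho(spec, th)) >= -1e-14))
  }
})

test_that("scad derivative is 1 up to lambda, 0 beyond a*lambda, linear between", {
  lam <- 0.8
  a <- 3.7
  spec <- penalty_spec("scad", lam, a = a)
  expect_equal(rho_prime(spec, lam / 2), 1)
  expect_equal(rho_prime(spec, lam), 1)
  expect_equal(rho_prime(spec, a * lam), 0)
  expect_equal(rho_prime(spec, a * lam + 2), 0)
  mid <- (lam + a * lam) / 2
  expect_equal(rho_prime(spec, mid), (a * lam - mid) / ((a - 1) * lam))
  expect_error(rho_prime(spec, 0), "> 0")
})

test_that("sica derivative is strictly decreasing with L1 limit", {
  spec <- penalty_spec("sica", 1, a = 2)
  th <- c(0.1, 0.5, 1, 3)
  expect_equal(rho_prime(spec, th), 2 * 3 / (2 + th)^2)
  expect_true(all(diff(rho_prime(spec, seq(0.01, 5, by = 0.01))) < 0))
  # a -> infinity recovers the lasso derivative
  spec_big <- penalty_spec("sica", 1, a = 1e8)
  expect_equal(rho_prime(spec_big, 1), 1, tolerance = 1e-7)
})

test_that("scad closed-form penalty equals the quadrature of its derivative", {
  set.seed(100)
  for (r in 1:50) {
    lam <- runif(1, 0.05, 2)
    a <- runif(1, 2.1, 6)
    theta <- runif(1, 0, 1.5 * a * lam)
    spec <- penalty_spec("scad", lam, a = a)
    # integrate piece by piece so the quadrature is exact at the kinks
    cuts <- unique(c(0, pmin(theta, c(lam, a * lam)), theta))
    cuts <- sort(cuts[cuts <= theta])
    quad <- 0
    for (k in seq_len(length(cuts) - 1L)) {
      quad <- quad + stats::integrate(function(s) lam * rho_prime(spec, s),
                                      lower = max(cuts[k], 1e-14),
                                      upper = cuts[k + 1L],
                                      rel.tol = 1e-12)$value
    }
    expect_equal(penalty_value(spec, theta), quad, tolerance = 1e-8)
  }
  # flat region value: lambda^2 (a+1) / 2
  spec <- penalty_spec("scad", 0.5, a = 3.7)
  expect_equal(penalty_value(spec, 10), 0.5^2 * 4.7 / 2)
})

test_that("lasso univariate minimizer is the soft threshold", {
  expect_equal(univariate_minimize(penalty_spec("lasso", 0), 2.4, 1.3),
               2.4 / 1.3)
  expect_equal(univariate_minimize(penalty_spec("lasso", 0.5), 2, 1), 1.5)
  expect_equal(univariate_minimize(penalty_spec("lasso", 0.5), -2, 1), -1.5)
  expect_equal(univariate_minimize(penalty_spec("lasso", 2), 1.5, 1), 0)
  expect_error(univariate_minimize(penalty_spec("lasso", 1), 1, 0), "vjj")
})

test_that("nonconvex univariate minimizers beat the grid-search oracle", {
  set.seed(200)
  for (r in 1:200) {
    v <- runif(1, -3, 3)
    vjj <- runif(1, 0.2, 2)
    lam <- runif(1, 0, 1)
    for (kind in c("scad", "sica")) {
      a <- if (kind == "scad") runif(1, 2.1, 8) else runif(1, 0.1, 10)
      spec <- penalty_spec(kind, lam, a = a)
      bhat <- univariate_minimize(spec, v, vjj)
      bstar <- grid_uni_min(spec, v, vjj)
      expect_lte(uni_objective(spec, v, vjj, bhat),
                 uni_objective(spec, v, vjj, bstar) + 1e-6)
    }
  }
})

test_that("univariate minimizer is odd in v and shrinks with lambda", {
  set.seed(300)
  for (r in 1:25) {
    v <- runif(1, 0.1, 3)
    vjj <- runif(1, 0.2, 2)
    for (kind in c("lasso", "scad", "sica")) {
      a <- if (kind == "scad") 3.7 else 1.5
      lams <- seq(0, 1.5, length.out = 12)
      prev <- Inf
      for (lam in lams) {
        spec <- penalty_spec(kind, lam, a = a)
        bp <- univariate_minimize(spec, v, vjj)
        bm <- univariate_minimize(spec, -v, vjj)
        expect_equal(bp, -bm, tolerance = 1e-12)
        expect_lte(abs(bp), prev + 1e-9)   # magnitude nonincreasing in lambda
        prev <- abs(bp)
      }
      # lambda = 0 reduces to the unpenalized minimizer
      expect_equal(univariate_minimize(penalty_spec(kind, 0, a = a), v, vjj),
                   v / vjj, tolerance = 1e-12)
    }
  }
})

test_that("sica at huge a matches the lasso minimizer", {
  set.seed(400)
  for (r in 1:40) {
    v <- runif(1, -3, 3)
    vjj <- runif(1, 0.2, 2)
    lam <- runif(1, 0, 1)
    got <- univariate_minimize(penalty_spec("sica", lam, a = 1e8), v, vjj)
    want <- univariate_minimize(penalty_spec("lasso", lam), v, vjj)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("default shapes follow the field conventions", {
  expect_equal(default_shape("scad"), 3.7)
  expect_equal(default_shape("sica"), c(0.01, 0.1, 1, 10, 100))
  expect_error(default_shape("lasso"), "no shape")
})
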