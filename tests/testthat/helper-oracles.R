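# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (fine-grid integration, exhaustive search) so they
# share no code path with the package internals they check.

# Riemann-sum approximation of the pseudo-score sufficient statistics
# on a fine midpoint grid (step * tau wide intervals).
riemann_suffstats <- function(time, status, Z, tau = max(time), step = 1e-4) {
  n <- length(time)
  p <- ncol(Z)
  h <- step * tau
  grid <- seq(h / 2, tau - h / 2, by = h)
  V <- matrix(0, p, p)
  for (t in grid) {
    ar <- which(time >= t)
    if (length(ar) == 0L) next
    zb <- colMeans(Z[ar, , drop = FALSE])
    Zc <- sweep(Z[ar, , drop = FALSE], 2L, zb)
    V <- V + crossprod(Zc) * h
  }
  b <- rep(0, p)
  for (i in which(status == 1 & time <= tau)) {
    ar <- which(time >= time[i])
    b <- b + (Z[i, ] - colMeans(Z[ar, , drop = FALSE]))
  }
  list(b = b / n, V = V / n)
}

# grid-search minimizer of the univariate penalized subproblem
grid_uni_min <- function(spec, v, vjj, lim = 10, step = 1e-4) {
  grid <- seq(-lim, lim, by = step)
  obj <- 0.5 * vjj * grid^2 - v * grid + penalty_value(spec, abs(grid))
  grid[which.min(obj)]
}

uni_objective <- function(spec, v, vjj, beta) {
  0.5 * vjj * beta^2 - v * beta + penalty_value(spec, abs(beta))
}

# exhaustive cumulative-case/dynamic-control AUC for uncensored data
pairwise_auc <- function(marker, time, status, t) {
  cases <- which(time <= t & status == 1)
  controls <- which(time > t)
  if (!length(cases) || !length(controls)) return(NA_real_)
  tot <- 0
  for (i in cases) {
    for (j in controls) {
      tot <- tot + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
    }
  }
  tot / (length(cases) * length(controls))
}

# small random survival dataset for property checks
random_dataset <- function(n, p, seed, censor_frac = 0.3) {
  set.seed(seed)
  time <- round(stats::rexp(n, 1) + 0.05, 3)
  status <- stats::rbinom(n, 1, 1 - censor_frac)
  if (all(status == 0)) status[sample(n, 1)] <- 1
  Z <- matrix(stats::rnorm(n * p), n, p)
  survival_dataset(time, status, Z)
}

# random PSD matrix plus ridge, for solver tests
random_psd <- function(p, seed, ridge = 0.1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p, p)
  crossprod(A) / p + ridge * diag(p)
}

# build an ah_suffstats object directly from (b, V) for solver tests
fake_suffstats <- function(b, V, n = 100L, tau = 1) {
  structure(list(b = b, V = V, Vdiag = diag(V), n = n, p = length(b),
                 tau = tau, feature_ids = paste0("f", seq_along(b)),
                 lowmem = FALSE, factors = NULL),
            class = "ah_suffstats")
}
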