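#' Configuration for the synthetic survival data generator
#'
#' Describes a high-dimensional gene-expression-like survival study:
#' correlated Gaussian covariates, an additive hazard
#' \eqn{\lambda(t; Z) = \lambda_0 + \beta'Z} with a sparse true
#' coefficient vector, and independent uniform censoring calibrated to a
#' target expected event count. The defaults mirror the motivating
#' oral-cancer cohort scale: 86 patients, 35 expected events, a few
#' thousand correlated features, and 5 truly active ones.
#'
#' @param n number of samples (default 86).
#' @param p number of features (default 2000; a full-scale study would
#'   use 29096).
#' @param n_true number of nonzero true coefficients (default 5).
#' @param beta_true optional explicit true coefficient p-vector;
#'   otherwise `n_true` entries at seed-drawn positions with magnitudes
#'   uniform in `beta_range` and random signs.
#' @param beta_range magnitude range for drawn true coefficients
#'   (default `c(0.5, 1)`).
#' @param rho AR(1) correlation between adjacent features, in \[0, 1)
#'   (default 0.3).
#' @param lambda0 constant baseline hazard rate (default 1); a
#'   piecewise-constant baseline is available via `baseline_breaks` /
#'   `baseline_rates`.
#' @param target_events expected number of observed events (default 35);
#'   must be at most n. `target_events = n` disables censoring.
#' @param clinical include four clinical covariates (age-like,
#'   3-level histology, two expression-like markers) with an additive
#'   hazard contribution `beta_clinical` on their standardized scale
#'   (default `TRUE`).
#' @param beta_clinical hazard contribution of the standardized clinical
#'   covariates (default `c(0.2, 0.2, 0.2, 0.2)`).
#' @param baseline_breaks,baseline_rates optional piecewise-constant
#'   baseline hazard: rate `baseline_rates[k]` on
#'   `[baseline_breaks[k-1], baseline_breaks[k])`, last rate extending to
#'   infinity; overrides `lambda0` when supplied.
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return an object of class `"ah_sim_config"`.
#' @export
ah_sim_config <- function(n = 86L, p = 2000L, n_true = 5L, beta_true = NULL,
                          beta_range = c(0.5, 1), rho = 0.3, lambda0 = 1,
                          target_events = 35L, clinical = TRUE,
                          beta_clinical = c(0.2, 0.2, 0.2, 0.2),
                          baseline_breaks = NULL, baseline_rates = NULL,
                          seed = 1L) {
  stopifnot_scalar(n, "n", positive = TRUE)
  stopifnot_scalar(p, "p", positive = TRUE)
  stopifnot_scalar(lambda0, "lambda0", positive = TRUE)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  if (target_events > n) {
    stop("'target_events' cannot exceed n", call. = FALSE)
  }
  if (target_events <= 0) stop("'target_events' must be positive", call. = FALSE)
  if (!is.null(beta_true) && length(beta_true) != p) {
    stop("'beta_true' must have length p", call. = FALSE)
  }
  if (xor(is.null(baseline_breaks), is.null(baseline_rates))) {
    stop("supply 'baseline_breaks' and 'baseline_rates' together",
         call. = FALSE)
  }
  if (!is.null(baseline_rates) &&
      length(baseline_rates) != length(baseline_breaks) + 1L) {
    stop("'baseline_rates' must have one more entry than 'baseline_breaks'",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_true = as.integer(n_true), beta_true = beta_true,
                 beta_range = beta_range, rho = rho, lambda0 = lambda0,
                 target_events = as.numeric(target_events),
                 clinical = isTRUE(clinical),
                 beta_clinical = beta_clinical,
                 baseline_breaks = baseline_breaks,
                 baseline_rates = baseline_rates,
                 seed = as.integer(seed)),
            class = "ah_sim_config")
}

#' @export
print.ah_sim_config <- function(x, ...) {
  cat(sprintf("Synthetic study config: n = %d, p = %d, %d true coefficients, rho = %.2g\n",
              x$n, x$p,
              if (is.null(x$beta_true)) x$n_true else sum(x$beta_true != 0),
              x$rho))
  cat(sprintf("  baseline hazard %s, target events %.3g, clinical = %s, seed = %d\n",
              if (is.null(x$baseline_rates)) sprintf("%.3g (constant)", x$lambda0)
              else "piecewise constant",
              x$target_events, x$clinical, x$seed))
  invisible(x)
}

# AR(1) Gaussian rows: z_1 ~ N(0,1), z_j = rho z_{j-1} + sqrt(1-rho^2) e_j
ar1_gaussian <- function(n, p, rho) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && p > 1L) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:p) Z[, j] <- rho * Z[, j - 1L] + sc * Z[, j]
  }
  Z
}

#' Synthetic clinical covariates
#'
#' Four baseline clinical covariates emulating the structure of an
#' oral-cancer chemoprevention cohort: a continuous age-like column
#' (normal, mean 60, SD 10), a 3-level ordinal histology grade, and two
#' continuous expression-like markers (standard normal). Deterministic
#' per seed.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return numeric matrix n x 4 with columns `age`, `histology`,
#'   `marker1`, `marker2` (empty matrix for `n = 0`).
#' @export
ah_simulate_clinical <- function(n, seed = 1L) {
  n <- as.integer(n)
  cn <- c("age", "histology", "marker1", "marker2")
  if (n == 0L) {
    return(matrix(numeric(0), 0L, 4L, dimnames = list(NULL, cn)))
  }
  with_seed(seed, {
    cbind(age = stats::rnorm(n, 60, 10),
          histology = as.numeric(sample(1:3, n, replace = TRUE,
                                        prob = c(0.5, 0.3, 0.2))),
          marker1 = stats::rnorm(n),
          marker2 = stats::rnorm(n))
  })
}

# piecewise-constant baseline cumulative hazard at time t (vectorized)
pc_cumhaz <- function(t, breaks, rates) {
  edges <- c(0, breaks, Inf)
  out <- numeric(length(t))
  for (k in seq_along(rates)) {
    lo <- edges[k]
    hi <- edges[k + 1L]
    out <- out + rates[k] * pmax(pmin(t, hi) - lo, 0)
  }
  out
}

# sample event times with hazard h_i + lambda0(t) (piecewise-constant
# baseline) by inversion of the cumulative hazard
sample_pc_times <- function(h, breaks, rates, u) {
  edges <- c(0, breaks, Inf)
  t_out <- numeric(length(h))
  target <- -log(u)
  for (i in seq_along(h)) {
    acc <- 0
    for (k in seq_along(rates)) {
      rate <- rates[k] + h[i]
      width <- edges[k + 1L] - edges[k]
      seg <- rate * width
      if (acc + seg >= target[i] || k == length(rates)) {
        t_out[i] <- edges[k] + (target[i] - acc) / rate
        break
      }
      acc <- acc + seg
    }
  }
  t_out
}

#' Generate a synthetic additive hazards survival dataset
#'
#' Covariate rows are zero-mean Gaussian with AR(1) covariance
#' \eqn{\rho^{|j-k|}}; the hazard of subject i is
#' \eqn{h_i = \lambda_0 + \beta_{true}'Z_i} (plus the clinical
#' contribution when configured). Subjects whose total covariate hazard
#' contribution would push the hazard at or below the floor
#' \eqn{0.01\lambda_0} are redrawn (rejection sampling keeps the law an
#' exact additive-hazards law conditional on acceptance; the count is
#' reported). Event times are exponential with rate \eqn{h_i} (or
#' piecewise-exponential under a piecewise-constant baseline); censoring
#' times are uniform on \eqn{(0, c)} with c solved numerically so the
#' expected observed event count equals `target_events`.
#'
#' @param cfg an [ah_sim_config()].
#' @return a list: `data` (a [survival_dataset()] with the clinical block
#'   attached when configured) and `truth` (`beta_true`, `lambda0` or the
#'   piecewise baseline, `beta_clinical`, censoring bound `c`,
#'   `rejections`, per-subject hazards `hazard`, and the seed).
#' @export
ah_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "ah_sim_config"))
  n <- cfg$n
  p <- cfg$p
  with_seed(cfg$seed, {
    beta_true <- cfg$beta_true
    if (is.null(beta_true)) {
      beta_true <- numeric(p)
      pos <- sample.int(p, cfg$n_true)
      beta_true[pos] <- sample(c(-1, 1), cfg$n_true, replace = TRUE) *
        stats::runif(cfg$n_true, cfg$beta_range[1L], cfg$beta_range[2L])
    }
    clinical <- NULL
    clin_std <- NULL
    if (cfg$clinical) {
      clinical <- ah_simulate_clinical(n, derive_seed(cfg$seed, 5L))
      clin_std <- standardize_columns(clinical)$x
    }
    base_rate0 <- if (is.null(cfg$baseline_rates)) cfg$lambda0
                  else min(cfg$baseline_rates)
    h_floor <- 0.01 * base_rate0
    active <- which(beta_true != 0)
    Z <- ar1_gaussian(n, p, cfg$rho)
    # covariate (plus clinical) contribution to the hazard, with
    # rejection of subjects violating the positivity floor
    contrib <- function(Zm, idx) {
      out <- if (length(active)) {
        drop(Zm[, active, drop = FALSE] %*% beta_true[active])
      } else numeric(nrow(Zm))
      if (!is.null(clin_std)) {
        out <- out + drop(clin_std[idx, , drop = FALSE] %*% cfg$beta_clinical)
      }
      out
    }
    eta <- contrib(Z, seq_len(n))
    rejections <- 0L
    bad <- which(base_rate0 + eta <= h_floor)
    while (length(bad)) {
      rejections <- rejections + length(bad)
      Z[bad, ] <- ar1_gaussian(length(bad), p, cfg$rho)
      eta[bad] <- contrib(Z[bad, , drop = FALSE], bad)
      bad <- bad[base_rate0 + eta[bad] <= h_floor]
      if (rejections > 1000L * n) {
        stop("hazard positivity rejection rate too high; ",
             "reduce |beta_true| or increase lambda0", call. = FALSE)
      }
    }
    u_event <- stats::runif(n)
    if (is.null(cfg$baseline_rates)) {
      h <- cfg$lambda0 + eta
      T_event <- -log(u_event) / h
      p_event <- function(cc) {
        # P(T <= C), C ~ U(0, cc), T ~ Exp(h): 1 - (1 - exp(-h cc))/(h cc)
        sum(1 - (1 - exp(-h * cc)) / (h * cc))
      }
    } else {
      h <- base_rate0 + eta  # reporting only; true hazard is time-varying
      T_event <- sample_pc_times(eta, cfg$baseline_breaks,
                                 cfg$baseline_rates, u_event)
      surv_t <- function(tt, i) exp(-(pc_cumhaz(tt, cfg$baseline_breaks,
                                                cfg$baseline_rates) +
                                        eta[i] * tt))
      p_event <- function(cc) {
        # P(T <= C) = 1 - (1/cc) * integral_0^cc S_i(t) dt, by quadrature
        sum(vapply(seq_len(n), function(i) {
          1 - stats::integrate(function(tt) surv_t(tt, i), 0, cc,
                               rel.tol = 1e-8)$value / cc
        }, numeric(1L)))
      }
    }
    if (cfg$target_events >= n) {
      C_cens <- rep(Inf, n)
      c_bound <- Inf
    } else {
      # achievable expected events approaches n as c -> Inf and 0 as
      # c -> 0; solve the monotone calibration equation for c
      f <- function(cc) p_event(cc) - cfg$target_events
      lo <- 1e-6
      hi <- 1
      while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
      if (f(hi) < 0) {
        stop(sprintf("target_events = %.3g is not achievable; at most %.3g expected events even without censoring",
                     cfg$target_events, p_event(1e8)), call. = FALSE)
      }
      c_bound <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
      C_cens <- stats::runif(n, 0, c_bound)
    }
    time <- pmin(T_event, C_cens)
    status <- as.numeric(T_event <= C_cens)
    feature_ids <- sprintf("g%04d", seq_len(p))
    names(beta_true) <- feature_ids
    data <- survival_dataset(time, status, Z, feature_ids = feature_ids,
                             clinical = clinical)
    list(data = data,
         truth = list(beta_true = beta_true,
                      lambda0 = cfg$lambda0,
                      baseline_breaks = cfg$baseline_breaks,
                      baseline_rates = cfg$baseline_rates,
                      beta_clinical = if (cfg$clinical) cfg$beta_clinical
                                      else NULL,
                      c = c_bound, rejections = rejections,
                      hazard = h, event_time = T_event,
                      seed = cfg$seed))
  })
}

#' Write a synthetic dataset in the package's exchange formats
#'
#' Expression as features-as-rows TSV, outcomes (time, status, clinical
#' columns) as CSV, and the ground-truth record as key/value text.
#'
#' @param sim result of [ah_simulate()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
ah_write_simulation <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data <- sim$data
  ids <- sprintf("S%04d", seq_len(data$n))
  ft <- feature_table(data$covariates, sample_ids = ids,
                      feature_ids = data$feature_ids)
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  write_expression(ft, expr_path)
  out <- data.frame(sample_id = ids, time = data$time, status = data$status)
  if (!is.null(data$clinical)) out <- cbind(out, as.data.frame(data$clinical))
  out_path <- file.path(dir, paste0(prefix, "_outcomes.csv"))
  write_outcomes(out, out_path)
  truth_path <- file.path(dir, paste0(prefix, "_truth.txt"))
  tr <- sim$truth
  nz <- which(tr$beta_true != 0)
  lines <- c(sprintf("seed\t%d", tr$seed),
             sprintf("lambda0\t%s", format(tr$lambda0, digits = 17)),
             sprintf("censoring_bound\t%s", format(tr$c, digits = 17)),
             sprintf("rejections\t%d", tr$rejections),
             sprintf("beta_true\t%s\t%s", names(tr$beta_true)[nz],
                     format(tr$beta_true[nz], digits = 17)))
  writeLines(lines, truth_path)
  invisible(c(expression = expr_path, outcomes = out_path,
              truth = truth_path))
}
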