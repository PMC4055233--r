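#' Penalized additive hazards fit at a single penalty setting
#'
#' Minimizes \eqn{Q(\beta) = L(\beta) + \sum_j p_\lambda(|\beta_j|)} with
#' \eqn{L(\beta) = \frac12\beta'V\beta - b'\beta} by cyclic coordinate
#' descent with exact coordinate minimization
#' ([univariate_minimize()]). Coordinates with \eqn{V_{jj} = 0} carry no
#' information and are frozen at 0. Convergence is declared when the
#' largest absolute coefficient change over a full sweep falls below
#' `tol`.
#'
#' @param ss an [ah_suffstats()] object.
#' @param spec a [penalty_spec()].
#' @param beta_init starting value (default all zeros).
#' @param tol convergence tolerance on coefficient change (default 1e-7).
#' @param max_sweeps sweep budget (default 10000).
#' @param active_set after two full sweeps, iterate over the nonzero set
#'   with full-sweep confirmation checks (default `TRUE`; the result
#'   agrees with plain cyclic descent to within `tol`).
#' @return an object of class `"ah_fit"`: `beta`, `spec`, `objective`,
#'   `objective_trace` (nonincreasing, one entry per sweep),
#'   `n_nonzero`, `sweeps`, `converged`.
#' @export
ah_fit <- function(ss, spec, beta_init = NULL, tol = 1e-7,
                   max_sweeps = 10000L, active_set = TRUE) {
  stopifnot(inherits(ss, "ah_suffstats"), inherits(spec, "penalty_spec"))
  p <- ss$p
  beta_init <- beta_init %||% numeric(p)
  if (length(beta_init) != p) stop("beta_init has wrong length", call. = FALSE)
  kind <- penalty_code(spec$penalty)
  a <- if (is.na(spec$a)) 0 else spec$a
  if (ss$lowmem) {
    f <- ss$factors
    res <- .cd_solve_lazy(ss$b, ss$Vdiag, f$Z, f$w, f$S, f$ck,
                          as.double(ss$n), kind, spec$lambda, a,
                          as.double(beta_init), tol,
                          as.integer(max_sweeps), isTRUE(active_set))
  } else {
    res <- .cd_solve(ss$b, ss$V, kind, spec$lambda, a, as.double(beta_init),
                     tol, as.integer(max_sweeps), isTRUE(active_set))
  }
  beta <- drop(res$beta)
  names(beta) <- ss$feature_ids
  structure(list(beta = beta, spec = spec,
                 objective = res$objective,
                 objective_trace = res$objective_trace,
                 n_nonzero = sum(beta != 0),
                 sweeps = res$sweeps,
                 converged = res$converged),
            class = "ah_fit")
}

#' @export
print.ah_fit <- function(x, ...) {
  cat(sprintf("Penalized additive hazards fit (%s, lambda = %.4g%s)\n",
              x$spec$penalty, x$spec$lambda,
              if (!is.na(x$spec$a)) sprintf(", a = %.4g", x$spec$a) else ""))
  cat(sprintf("  %d nonzero of %d coefficients; Q = %.6g; %d sweeps (%s)\n",
              x$n_nonzero, length(x$beta), x$objective, x$sweeps,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Default decreasing lambda grid
#'
#' From \eqn{\lambda_{max} = \max_j |b_j|} (the smallest lambda at which
#' the lasso solution is identically zero) down to
#' `lambda_min_ratio * lambda_max`, log-spaced.
#'
#' @param ss an [ah_suffstats()] object.
#' @param nlambda number of grid points (default 50).
#' @param lambda_min_ratio smallest/largest lambda ratio (default 0.01).
#' @return strictly decreasing numeric vector.
#' @export
default_lambda_grid <- function(ss, nlambda = 50L, lambda_min_ratio = 0.01) {
  lam_max <- max(abs(ss$b))
  if (lam_max == 0) lam_max <- 1  # no events: any lambda keeps beta = 0
  grid <- exp(seq(log(lam_max), log(lambda_min_ratio * lam_max),
                  length.out = nlambda))
  grid[1L] <- lam_max  # exp(log(x)) can lose an ulp; the endpoint is exact
  grid
}

#' Warm-started regularization path
#'
#' Fits the penalty over a strictly decreasing lambda grid, using each
#' solution to initialize the next (for the nonconvex penalties this
#' anchors the path at the sparse, lasso-like large-lambda end).
#'
#' @param ss an [ah_suffstats()] object.
#' @param penalty `"lasso"`, `"scad"` or `"sica"`.
#' @param lambda strictly decreasing grid; default
#'   [default_lambda_grid()].
#' @param a shape parameter (see [penalty_spec()]).
#' @param warm_start initialize each fit from the previous solution
#'   (default `TRUE`).
#' @inheritParams ah_fit
#' @return list of [ah_fit()] results in grid order, with the grid as
#'   attribute `"lambda"`.
#' @export
ah_path <- function(ss, penalty = c("lasso", "scad", "sica"), lambda = NULL,
                    a = NULL, tol = 1e-7, max_sweeps = 10000L,
                    warm_start = TRUE, active_set = TRUE) {
  penalty <- match.arg(penalty)
  lambda <- lambda %||% default_lambda_grid(ss)
  if (length(lambda) == 0L) stop("empty lambda grid", call. = FALSE)
  if (length(lambda) > 1L && any(diff(lambda) >= 0)) {
    stop("'lambda' must be strictly decreasing", call. = FALSE)
  }
  fits <- vector("list", length(lambda))
  if (ss$lowmem) {
    # single compiled call: the on-demand column cache of V is shared
    # across the whole path
    spec1 <- penalty_spec(penalty, lambda[1L], a)
    f <- ss$factors
    res <- .cd_path_lazy(ss$b, ss$Vdiag, f$Z, f$w, f$S, f$ck,
                         as.double(ss$n), penalty_code(penalty),
                         as.double(lambda),
                         if (is.na(spec1$a)) 0 else spec1$a,
                         tol, as.integer(max_sweeps), isTRUE(active_set),
                         isTRUE(warm_start))
    for (k in seq_along(lambda)) {
      beta <- res$beta[, k]
      names(beta) <- ss$feature_ids
      fits[[k]] <- structure(
        list(beta = beta, spec = penalty_spec(penalty, lambda[k], a),
             objective = res$objective[k],
             objective_trace = res$traces[[k]],
             n_nonzero = sum(beta != 0),
             sweeps = res$sweeps[k],
             converged = res$converged[k]),
        class = "ah_fit")
    }
  } else {
    beta <- numeric(ss$p)
    for (k in seq_along(lambda)) {
      spec <- penalty_spec(penalty, lambda[k], a)
      fits[[k]] <- ah_fit(ss, spec,
                          beta_init = if (warm_start) beta else NULL,
                          tol = tol, max_sweeps = max_sweeps,
                          active_set = active_set)
      beta <- fits[[k]]$beta
    }
  }
  attr(fits, "lambda") <- lambda
  attr(fits, "penalty") <- penalty
  fits
}
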