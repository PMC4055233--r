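#' Fit a sparse penalized additive hazards regression path
#'
#' The main fitting function of the package. Under the additive hazards
#' model the hazard of subject \eqn{i} is
#' \eqn{\lambda(t; Z_i) = \lambda_0(t) + \beta' Z_i}: covariate effects
#' add to the baseline hazard rather than multiplying it. The regression
#' coefficients solve the penalized least-squares-type problem
#' \deqn{\hat\beta = \arg\min_\beta \; \tfrac12 \beta' V \beta - b'\beta
#'   + \sum_j p_\lambda(|\beta_j|)}
#' where \eqn{(b, V)} are the pseudo-score sufficient statistics
#' ([ah_suffstats()]) and \eqn{p_\lambda} is one of the lasso, SCAD or
#' SICA penalties ([penalty_spec()]). The whole regularization path over
#' a decreasing lambda grid is returned, fitted by warm-started cyclic
#' coordinate descent.
#'
#' @param x covariate matrix (samples in rows) or a
#'   [survival_dataset()] (in which case `time`/`status` are ignored).
#' @param time,status follow-up times and 0/1 event indicators.
#' @param penalty `"lasso"`, `"scad"` or `"sica"`.
#' @param lambda optional strictly decreasing grid; by default `nlambda`
#'   log-spaced values from \eqn{\lambda_{max} = \max_j |b_j|} down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio grid shape when `lambda` is `NULL`.
#' @param a penalty shape parameter (SCAD default 3.7; SICA default 1).
#' @param standardize center and scale covariate columns before fitting
#'   (default `TRUE`; penalized estimates are scale-sensitive).
#'   Coefficients are reported on both scales.
#' @param tau integration horizon (default: last observed time).
#' @param tol,max_sweeps coordinate descent controls, see [ah_fit()].
#' @return an object of class `"ahpen"` with components `beta`
#'   (p x nlambda matrix, original covariate scale), `beta_std`
#'   (standardized scale), `lambda`, `penalty`, `a`, `df` (nonzeros per
#'   lambda), `loss`, `objective`, `center`, `scale`, `suffstats`,
#'   `data`, `call`.
#' @seealso [ah_cv()] for cross-validated tuning, [predict.ahpen()],
#'   [ah_cumhaz()].
#' @examples
#' sim <- ah_simulate(ah_sim_config(n = 100, p = 20, seed = 1))
#' fit <- ahpen(sim$data, penalty = "lasso")
#' print(fit)
#' coef(fit, s = fit$lambda[10])[1:5]
#' @export
ahpen <- function(x, time = NULL, status = NULL,
                  penalty = c("lasso", "scad", "sica"),
                  lambda = NULL, nlambda = 50L, lambda_min_ratio = 0.01,
                  a = NULL, standardize = TRUE, tau = NULL,
                  tol = 1e-7, max_sweeps = 10000L) {
  penalty <- match.arg(penalty)
  cl <- match.call()
  if (inherits(x, "survival_dataset")) {
    data <- x
    center <- attr(data, "center") %||% rep(0, data$p)
    scale <- attr(data, "scale") %||% rep(1, data$p)
  } else {
    x <- as.matrix(x)
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
    if (standardize) {
      std <- standardize_columns(x)
      x <- std$x
      center <- std$center
      scale <- std$scale
    }
    data <- survival_dataset(time, status, x, tau = tau)
    attr(data, "center") <- center
    attr(data, "scale") <- scale
    attr(data, "standardized") <- standardize
  }
  ss <- ah_suffstats(data)
  lambda <- lambda %||% default_lambda_grid(ss, nlambda, lambda_min_ratio)
  fits <- ah_path(ss, penalty, lambda = lambda, a = a, tol = tol,
                  max_sweeps = max_sweeps)
  beta_std <- vapply(fits, function(f) f$beta, numeric(ss$p))
  if (ss$p == 1L) beta_std <- matrix(beta_std, nrow = 1L)
  rownames(beta_std) <- ss$feature_ids
  colnames(beta_std) <- format(lambda, digits = 4)
  beta_orig <- beta_std / scale
  structure(list(beta = beta_orig, beta_std = beta_std, lambda = lambda,
                 penalty = penalty,
                 a = if (penalty == "lasso") NA_real_
                     else fits[[1L]]$spec$a,
                 df = vapply(fits, function(f) f$n_nonzero, integer(1L)),
                 loss = vapply(fits, function(f) ah_loss(f$beta, ss),
                               numeric(1L)),
                 objective = vapply(fits, function(f) f$objective,
                                    numeric(1L)),
                 converged = vapply(fits, function(f) f$converged,
                                    logical(1L)),
                 center = center, scale = scale,
                 suffstats = ss, data = data, call = cl),
            class = "ahpen")
}

#' @export
print.ahpen <- function(x, ...) {
  cat(sprintf("Penalized additive hazards path: %s penalty%s\n", x$penalty,
              if (!is.na(x$a)) sprintf(" (a = %.4g)", x$a) else ""))
  cat(sprintf("  n = %d, p = %d, %d lambda values in [%.4g, %.4g]\n",
              x$data$n, x$data$p, length(x$lambda),
              min(x$lambda), max(x$lambda)))
  cat(sprintf("  df range along the path: %d .. %d\n",
              min(x$df), max(x$df)))
  invisible(x)
}

#' @export
summary.ahpen <- function(object, ...) {
  out <- data.frame(lambda = object$lambda, df = object$df,
                    loss = object$loss, objective = object$objective,
                    converged = object$converged)
  class(out) <- c("summary.ahpen", "data.frame")
  out
}

#' @export
print.summary.ahpen <- function(x, ...) {
  cat("Path summary (one row per lambda):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# nearest path index for a requested lambda value
lambda_index <- function(object, s) {
  if (is.null(s)) return(length(object$lambda))
  which.min(abs(object$lambda - s))
}

#' Extract coefficients from an ahpen path
#'
#' @param object an `"ahpen"` fit.
#' @param s lambda value (nearest grid point is used); default the
#'   smallest lambda on the path.
#' @param scale `"original"` (default) or `"standardized"`.
#' @param ... unused.
#' @return named coefficient vector.
#' @export
coef.ahpen <- function(object, s = NULL,
                       scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  k <- lambda_index(object, s)
  if (scale == "original") object$beta[, k] else object$beta_std[, k]
}

#' Predict from an ahpen fit
#'
#' @param object an `"ahpen"` fit.
#' @param newx covariate matrix on the original scale (standardization
#'   learned at fit time is applied); defaults to the training matrix.
#' @param s lambda value (nearest grid point).
#' @param type `"link"` for the linear risk score \eqn{\beta'z},
#'   `"survival"` for predicted survival probabilities over `times`
#'   (via the estimated baseline cumulative hazard, see [ah_cumhaz()]),
#'   `"coefficients"`, or `"nonzero"` for the selected feature ids.
#' @param times evaluation times for `type = "survival"`.
#' @param ... unused.
#' @return vector, matrix (samples x times for `"survival"`) or id
#'   vector, by `type`.
#' @export
predict.ahpen <- function(object, newx = NULL, s = NULL,
                          type = c("link", "survival", "coefficients",
                                   "nonzero"),
                          times = NULL, ...) {
  type <- match.arg(type)
  k <- lambda_index(object, s)
  if (type == "coefficients") return(object$beta[, k])
  if (type == "nonzero") {
    return(object$suffstats$feature_ids[object$beta_std[, k] != 0])
  }
  beta_std <- object$beta_std[, k]
  if (is.null(newx)) {
    zstd <- object$data$covariates
  } else {
    newx <- as.matrix(newx)
    zstd <- apply_standardization(newx, object$center, object$scale)
  }
  link <- drop(zstd %*% beta_std)
  if (type == "link") return(link)
  times <- times %||% sort(unique(object$data$time[object$data$status == 1]))
  ch <- ah_cumhaz(object$data, beta_std)
  predict_survival(beta_std, ch, zstd, times)
}

#' Martingale-type residuals for an ahpen fit
#'
#' \eqn{\Delta_i - \hat\Lambda(X_i \mid Z_i)} where
#' \eqn{\hat\Lambda(t|z) = \hat\Lambda_0(t) + (\beta'z)t} is the fitted
#' cumulative hazard.
#'
#' @param object an `"ahpen"` fit.
#' @param s lambda value (nearest grid point).
#' @param ... unused.
#' @return numeric vector, one residual per training sample.
#' @export
residuals.ahpen <- function(object, s = NULL, ...) {
  k <- lambda_index(object, s)
  beta_std <- object$beta_std[, k]
  data <- object$data
  ch <- ah_cumhaz(data, beta_std)
  lp <- drop(data$covariates %*% beta_std)
  cum <- evaluate_cumhaz(ch, data$time) + lp * data$time
  data$status - cum
}

#' Plot an ahpen coefficient path
#'
#' Coefficient profiles (standardized scale) against log lambda, one
#' line per feature ever active along the path.
#'
#' @param x an `"ahpen"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ahpen <- function(x, ...) {
  active <- rowSums(x$beta_std != 0) > 0
  if (!any(active)) {
    warning("no feature is active anywhere on the path; nothing to plot")
    return(invisible(x))
  }
  graphics::matplot(log(x$lambda), t(x$beta_std[active, , drop = FALSE]),
                    type = "l", lty = 1,
                    xlab = expression(log(lambda)),
                    ylab = "standardized coefficient",
                    main = sprintf("%s coefficient path", x$penalty), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
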