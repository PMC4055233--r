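#' Penalty specification for sparse additive hazards regression
#'
#' Three penalty families are supported, each used as
#' \eqn{p_\lambda(\theta) = \lambda\,\rho(\theta)} on
#' \eqn{\theta = |\beta_j|}:
#' \describe{
#'   \item{lasso}{\eqn{\rho(\theta) = \theta} (convex L1).}
#'   \item{scad}{defined through its derivative
#'     \eqn{\rho'_\lambda(\theta) = I(\theta \le \lambda) +
#'     \frac{(a\lambda - \theta)_+}{(a-1)\lambda} I(\theta > \lambda)}
#'     with shape \eqn{a > 2} (default 3.7); \eqn{\rho} is its integral,
#'     fixed by \eqn{\rho(0) = 0}, so the penalty is linear, then
#'     quadratic, then constant at \eqn{\lambda(a+1)/2}.}
#'   \item{sica}{\eqn{\rho(\theta) = (a+1)\theta/(a+\theta)} with shape
#'     \eqn{a > 0}; interpolates between an L0-like penalty (small a) and
#'     the L1 penalty (large a).}
#' }
#'
#' @param penalty one of `"lasso"`, `"scad"`, `"sica"`.
#' @param lambda regularization parameter, \eqn{\lambda \ge 0}.
#' @param a shape parameter; ignored for lasso, default 3.7 for SCAD
#'   (must be > 2), required > 0 for SICA (default 1).
#' @return an object of class `"penalty_spec"`.
#' @export
penalty_spec <- function(penalty = c("lasso", "scad", "sica"), lambda, a = NULL) {
  penalty <- match.arg(penalty)
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  if (penalty == "lasso") {
    a <- NA_real_
  } else if (penalty == "scad") {
    a <- a %||% 3.7
    stopifnot_scalar(a, "a")
    if (a <= 2) stop("SCAD requires shape parameter a > 2", call. = FALSE)
  } else {
    a <- a %||% 1
    stopifnot_scalar(a, "a")
    if (a <= 0) stop("SICA requires shape parameter a > 0", call. = FALSE)
  }
  structure(list(penalty = penalty, lambda = lambda, a = a),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("Penalty: %s, lambda = %.4g%s\n", x$penalty, x$lambda,
              if (!is.na(x$a)) sprintf(", a = %.4g", x$a) else ""))
  invisible(x)
}

penalty_code <- function(penalty) {
  match(penalty, c("lasso", "scad", "sica")) - 1L
}

#' Penalty generator rho and its derivative
#'
#' `rho()` returns \eqn{\rho(\theta)} such that the penalty used in the
#' objective is \eqn{p_\lambda(\theta) = \lambda\rho(\theta)} uniformly
#' across families (for SCAD, \eqn{\rho} therefore depends on
#' \eqn{\lambda}: it is the closed-form integral of the printed
#' \eqn{\rho'_\lambda}). `rho_prime()` returns \eqn{\rho'(\theta)}:
#' constant 1 for lasso, the clipped-linear SCAD form, and
#' \eqn{a(a+1)/(a+\theta)^2} for SICA (strictly decreasing, with L1
#' limit 1 as \eqn{a \to \infty}).
#'
#' @param spec a [penalty_spec()].
#' @param theta nonnegative magnitude(s) \eqn{|\beta_j|} (`rho_prime`
#'   requires strictly positive values; the behaviour at 0 belongs to the
#'   thresholding operator, not the derivative).
#' @return numeric vector of the same length as `theta`.
#' @export
rho <- function(spec, theta) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(theta < 0)) stop("'theta' must be >= 0 (pass |beta|)", call. = FALSE)
  switch(spec$penalty,
    lasso = theta,
    sica = (spec$a + 1) * theta / (spec$a + theta),
    scad = {
      if (spec$lambda == 0) {
        # rho = integral of rho'_lambda; in the lambda -> 0 limit the
        # penalty vanishes for any theta > 0
        ifelse(theta == 0, 0, 0)
      } else {
        .cd_pen_value(1L, spec$lambda, spec$a, theta) / spec$lambda
      }
    })
}

#' @rdname rho
#' @export
rho_prime <- function(spec, theta) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(theta <= 0)) stop("'theta' must be > 0", call. = FALSE)
  switch(spec$penalty,
    lasso = rep(1, length(theta)),
    sica = spec$a * (spec$a + 1) / (spec$a + theta)^2,
    scad = {
      lam <- spec$lambda
      a <- spec$a
      if (lam == 0) rep(0, length(theta))
      else ifelse(theta <= lam, 1,
                  pmax(a * lam - theta, 0) / ((a - 1) * lam))
    })
}

#' Penalty value \eqn{p_\lambda(\theta)}
#'
#' @inheritParams rho
#' @return \eqn{\lambda \rho(\theta)} evaluated in closed form.
#' @export
penalty_value <- function(spec, theta) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(theta < 0)) stop("'theta' must be >= 0 (pass |beta|)", call. = FALSE)
  .cd_pen_value(penalty_code(spec$penalty), spec$lambda,
                if (is.na(spec$a)) 0 else spec$a, theta)
}

#' Exact univariate penalized minimizer
#'
#' Returns \eqn{\arg\min_\beta \; \frac12 v_{jj}\beta^2 - v\beta +
#' p_\lambda(|\beta|)}, the subproblem each coordinate-descent step
#' solves. The lasso case is the closed-form soft threshold
#' \eqn{\mathrm{sign}(v)(|v| - \lambda)_+ / v_{jj}}; SCAD and SICA are
#' solved exactly by enumerating the stationary points of every smooth
#' piece (closed-form cubic roots for SICA) together with the piece
#' boundaries and 0, and returning the best. Ties between 0 and a nonzero
#' candidate resolve to 0.
#'
#' @param spec a [penalty_spec()].
#' @param v linear coefficient of the subproblem.
#' @param vjj positive quadratic coefficient.
#' @return scalar minimizer.
#' @export
univariate_minimize <- function(spec, v, vjj) {
  stopifnot(inherits(spec, "penalty_spec"))
  stopifnot_scalar(v, "v")
  stopifnot_scalar(vjj, "vjj", positive = TRUE)
  .cd_uni_min(penalty_code(spec$penalty), spec$lambda,
              if (is.na(spec$a)) 0 else spec$a, v, vjj)
}

#' Default shape parameter for a penalty family
#'
#' SCAD uses the conventional a = 3.7; SICA has no single default and
#' returns the log-spaced grid `c(0.01, 0.1, 1, 10, 100)` over which the
#' shape is tuned jointly with lambda by cross-validation.
#'
#' @param penalty `"scad"` or `"sica"` (lasso has no shape parameter and
#'   is an error).
#' @return scalar (scad) or numeric grid (sica).
#' @export
default_shape <- function(penalty = c("scad", "sica")) {
  if (identical(penalty, "lasso")) {
    stop("the lasso penalty has no shape parameter", call. = FALSE)
  }
  penalty <- match.arg(penalty)
  if (penalty == "scad") 3.7 else c(0.01, 0.1, 1, 10, 100)
}
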