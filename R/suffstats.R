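#' Sufficient statistics of the additive hazards least-squares loss
#'
#' Reduces a survival dataset to the pair \eqn{(b, V)} that the
#' least-squares-type loss \eqn{L(\beta) = \frac12 \beta' V \beta - b'\beta}
#' is built from:
#' \deqn{b = \frac1n \sum_i \int_0^\tau \{Z_i - \bar Z(t)\}\, dN_i(t), \qquad
#'       V = \frac1n \sum_i \int_0^\tau Y_i(t)\{Z_i - \bar Z(t)\}
#'           \{Z_i - \bar Z(t)\}' \, dt,}
#' with at-risk indicator \eqn{Y_i(t) = I(X_i \ge t)} and risk-set mean
#' \eqn{\bar Z(t)}. Both integrals are evaluated exactly: the risk set is
#' piecewise constant between consecutive distinct observed times, so
#' \eqn{V} is a finite sum of duration-weighted centered scatter matrices.
#' Internally this collapses to two crossproducts,
#' \eqn{nV = Z' \mathrm{diag}(w) Z - S' \mathrm{diag}(c) S}, where
#' \eqn{w_i = \min(X_i, \tau)} is subject i's at-risk duration, row k of
#' \eqn{S} is the covariate column sum over the k-th risk set and
#' \eqn{c_k = \Delta t_k / n_k}.
#'
#' Events at exactly \eqn{t = \tau} are counted; if \eqn{\tau} exceeds the
#' last observed time the duration integral is truncated there (empty risk
#' set) with a warning, and a dataset with no events yields \eqn{b = 0}
#' with a warning.
#'
#' @param data a [survival_dataset()].
#' @param lowmem if `TRUE`, store only `diag(V)` plus the factors needed
#'   to reconstruct arbitrary columns of `V` on demand, bounding memory at
#'   O(np) for very large p. Both representations give identical results.
#' @return an object of class `"ah_suffstats"` with components `b`
#'   (p-vector), `V` (p x p matrix, or `NULL` under `lowmem`), `Vdiag`,
#'   `n`, `tau`, and (under `lowmem`) the column factors.
#' @export
ah_suffstats <- function(data, lowmem = FALSE) {
  stopifnot(inherits(data, "survival_dataset"))
  x <- data$time
  status <- data$status
  Z <- data$covariates
  n <- data$n
  p <- data$p
  tau <- data$tau
  if (tau > max(x)) {
    warning("tau exceeds the last observed time; ",
            "integration truncated at the last at-risk time")
  }
  if (sum(status) == 0) warning("dataset has no events: b is the zero vector")

  # order subjects by decreasing time; risk sets grow as we walk the
  # distinct times downward
  ord <- order(x, decreasing = TRUE)
  xs <- x[ord]
  Zs <- Z[ord, , drop = FALSE]

  # interval grid on [0, min(tau, max x)]: breakpoints at distinct
  # observed times <= tau (clipped at tau if tau lies below some times)
  ut <- sort(unique(x))
  upper <- min(tau, max(x))
  breaks <- c(ut[ut < upper], upper)          # right endpoints, increasing
  K <- length(breaks)
  widths <- diff(c(0, breaks))
  # risk set for interval (breaks[k-1], breaks[k]] is {i : X_i >= breaks[k]}
  nk <- vapply(breaks, function(tk) sum(xs >= tk), integer(1L))

  # cumulative column sums over sorted rows: S[k, ] = colSums over the
  # nk[k] largest times
  cs <- apply(Zs, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)  # n = 1 or p = 1
  S <- cs[nk, , drop = FALSE]
  ck <- widths / nk

  w <- pmin(x, tau)                           # per-subject at-risk duration
  Vdiag_full <- NULL
  if (lowmem) {
    V <- NULL
    Vdiag <- (colSums(Z * Z * w) - colSums(S * S * ck)) / n
  } else {
    V <- (crossprod(Z, Z * w) - crossprod(S, S * ck)) / n
    V <- (V + t(V)) / 2                        # enforce exact symmetry
    Vdiag <- diag(V)
  }

  # b: event-time jumps of the centered counting-process integral;
  # the risk-set mean at an event time is a cumulative-sum row over the
  # time-sorted covariates
  b <- numeric(p)
  ev <- which(status == 1 & x <= tau)
  if (length(ev)) {
    m_ev <- n - rank(x, ties.method = "min")[ev] + 1L  # |{X >= X_i}|
    zbar_sum <- crossprod(cs[m_ev, , drop = FALSE], 1 / m_ev)
    b <- (colSums(Z[ev, , drop = FALSE]) - drop(zbar_sum)) / n
  }
  names(b) <- data$feature_ids
  structure(list(b = b, V = V, Vdiag = Vdiag, n = n, p = p, tau = tau,
                 feature_ids = data$feature_ids,
                 lowmem = lowmem,
                 factors = if (lowmem) list(Z = Z, w = w, S = S, ck = ck)
                           else NULL),
            class = "ah_suffstats")
}

#' @export
print.ah_suffstats <- function(x, ...) {
  cat(sprintf("Additive hazards sufficient statistics: p = %d, n = %d, tau = %.3g%s\n",
              x$p, x$n, x$tau,
              if (x$lowmem) " (low-memory representation)" else ""))
  invisible(x)
}

# column j of V, identical for both representations
ah_v_column <- function(ss, j) {
  if (!ss$lowmem) return(ss$V[, j])
  f <- ss$factors
  (crossprod(f$Z, f$w * f$Z[, j]) - crossprod(f$S, f$ck * f$S[, j]))[, 1L] / ss$n
}

# V %*% beta without materializing V under lowmem
ah_v_times <- function(ss, beta) {
  if (!ss$lowmem) return(drop(ss$V %*% beta))
  f <- ss$factors
  u <- drop(f$Z %*% beta)
  v <- drop(f$S %*% beta)
  drop(crossprod(f$Z, f$w * u) - crossprod(f$S, f$ck * v)) / ss$n
}

#' Least-squares-type loss of the additive hazards model
#'
#' \eqn{L(\beta) = \frac12 \beta' V \beta - b' \beta}; the negative
#' antiderivative of the pseudo-score \eqn{U(\beta) = b - V\beta}. May be
#' negative; `ah_loss(0, ss)` is exactly 0.
#'
#' @param beta coefficient vector of length p.
#' @param ss an [ah_suffstats()] object.
#' @return scalar loss value.
#' @export
ah_loss <- function(beta, ss) {
  stopifnot(inherits(ss, "ah_suffstats"))
  if (length(beta) != ss$p) {
    stop(sprintf("beta has length %d but suffstats have p = %d",
                 length(beta), ss$p), call. = FALSE)
  }
  if (all(beta == 0)) return(0)
  0.5 * sum(beta * ah_v_times(ss, beta)) - sum(ss$b * beta)
}

#' Pseudo-score of the additive hazards model
#'
#' \eqn{U(\beta) = b - V\beta}; its root is the unpenalized estimator.
#'
#' @inheritParams ah_loss
#' @return p-vector.
#' @export
ah_score <- function(beta, ss) {
  stopifnot(inherits(ss, "ah_suffstats"))
  if (length(beta) != ss$p) stop("dimension mismatch", call. = FALSE)
  ss$b - ah_v_times(ss, beta)
}

#' Unpenalized additive hazards estimator
#'
#' Solves the pseudo-score equation \eqn{V\beta = b}. When `V` is
#' numerically singular the minimum-norm solution is returned and the
#' result is flagged with attribute `"rank_deficient"`.
#'
#' @param ss an [ah_suffstats()] object (dense representation).
#' @param tol relative singular-value tolerance for rank detection.
#' @return p-vector with attributes `"rank"` and `"rank_deficient"`.
#' @export
ah_lsfit <- function(ss, tol = 1e-10) {
  stopifnot(inherits(ss, "ah_suffstats"))
  if (is.null(ss$V)) stop("ah_lsfit requires the dense V representation",
                          call. = FALSE)
  if (all(ss$b == 0)) {
    beta <- numeric(ss$p)
  } else {
    sv <- svd(ss$V)
    keep <- sv$d > tol * max(sv$d)
    dinv <- ifelse(keep, 1 / sv$d, 0)
    beta <- drop(sv$v %*% (dinv * crossprod(sv$u, ss$b)))
  }
  names(beta) <- ss$feature_ids
  rank <- if (all(ss$b == 0)) ss$p else sum(keep)
  attr(beta, "rank") <- rank
  attr(beta, "rank_deficient") <- rank < ss$p
  beta
}
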