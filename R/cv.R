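# Stratified fold assignment: events and censored samples are spread
# separately across folds so every fold (and hence every training set)
# contains events whenever K <= number of events.
make_folds <- function(status, K, seed) {
  n <- length(status)
  fold <- integer(n)
  with_seed(seed, {
    # shuffle within status groups, then deal the concatenated order
    # round-robin across folds: folds stay balanced overall and events
    # are spread as evenly as possible
    shuf <- function(ix) if (length(ix) <= 1L) ix else sample(ix)
    ord <- c(shuf(which(status == 1)), shuf(which(status == 0)))
    fold[ord] <- rep_len(seq_len(K), n)
  })
  fold
}

#' Cross-validated tuning of the penalty
#'
#' K-fold cross-validation of lambda (and, for SICA, jointly of the
#' shape parameter a) using the least-squares-type loss as score:
#' \deqn{CV(\lambda) = \frac1K \sum_{m=1}^K L^{(m)}(\hat\beta^{(-m)}(\lambda)),}
#' where \eqn{\hat\beta^{(-m)}} is fit on the data with fold m removed
#' and \eqn{L^{(m)}} is the loss built from the sufficient statistics of
#' fold m alone. Folds are stratified by event status. Ties in the CV
#' minimum break toward larger lambda (the sparser model), then toward
#' larger a. A grid point whose fit fails to converge in any fold is
#' scored `+Inf` and can never be selected (a guard against the
#' instability of SICA at very small a).
#'
#' @param data a [survival_dataset()].
#' @param penalty `"lasso"`, `"scad"` or `"sica"`.
#' @param lambda strictly decreasing grid; default
#'   [default_lambda_grid()] on the full data with `nlambda` points.
#' @param nlambda,lambda_min_ratio shape of the default grid.
#' @param a_values shape grid; defaults to 3.7 for SCAD and
#'   [default_shape]`("sica")` for SICA.
#' @param nfolds number of folds K (default 10; `nfolds = n` gives
#'   leave-one-out).
#' @param seed fold-assignment seed (all randomness in this function
#'   flows from it).
#' @param tol,max_sweeps coordinate descent controls.
#' @param lowmem use the lazy-column representation of V for the fold
#'   fits (`NULL`, the default, chooses it automatically when
#'   p > max(500, 2n); both representations give identical fits).
#' @return an object of class `"ah_cv"`: `lambda`, `a_values`,
#'   `score_grid` (lambda x a matrix of CV scores), `selected_lambda`,
#'   `selected_a`, `selected_beta` (full-data fit at the selected
#'   point, standardized scale), `fold_assignment`, `seed`, `penalty`,
#'   `full_path` (list over `a_values` of [ah_path()] results on the
#'   full data).
#' @examples
#' sim <- ah_simulate(ah_sim_config(n = 120, p = 15, seed = 7))
#' cv <- ah_cv(sim$data, "lasso", nfolds = 5, seed = 7)
#' cv$selected_lambda
#' @export
ah_cv <- function(data, penalty = c("lasso", "scad", "sica"), lambda = NULL,
                  a_values = NULL, nfolds = 10L, seed = 1L,
                  nlambda = 50L, lambda_min_ratio = 0.01,
                  tol = 1e-7, max_sweeps = 10000L, lowmem = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(data, "survival_dataset"))
  n <- data$n
  if (nfolds < 2L || nfolds > n) {
    stop("'nfolds' must be between 2 and n", call. = FALSE)
  }
  if (sum(data$status) < 1L) stop("cross-validation needs at least one event",
                                  call. = FALSE)
  a_values <- a_values %||% switch(penalty, lasso = NA_real_,
                                   scad = default_shape("scad"),
                                   sica = default_shape("sica"))
  lowmem <- lowmem %||% (data$p > max(500L, 2L * n))
  ss_full <- suppressWarnings(ah_suffstats(data, lowmem = lowmem))
  lambda <- lambda %||% default_lambda_grid(ss_full, nlambda,
                                            lambda_min_ratio)

  # draw folds; every training set must contain at least one event
  fold <- NULL
  for (attempt in 0:9) {
    cand <- make_folds(data$status, nfolds, derive_seed(seed, 1L, attempt))
    train_ok <- vapply(seq_len(nfolds), function(m) {
      sum(data$status[cand != m]) >= 1
    }, logical(1L))
    if (all(train_ok)) { fold <- cand; break }
  }
  if (is.null(fold)) {
    stop("could not draw folds whose training sets all contain events",
         call. = FALSE)
  }

  nl <- length(lambda)
  na <- length(a_values)
  score <- matrix(0, nl, na,
                  dimnames = list(format(lambda, digits = 4),
                                  format(a_values, digits = 4)))
  diverged <- matrix(FALSE, nl, na)
  for (m in seq_len(nfolds)) {
    train <- subset_dataset(data, fold != m)
    test <- subset_dataset(data, fold == m)
    ss_tr <- suppressWarnings(ah_suffstats(train, lowmem = lowmem))
    ss_te <- suppressWarnings(ah_suffstats(test, lowmem = lowmem))
    for (ai in seq_len(na)) {
      fits <- ah_path(ss_tr, penalty, lambda = lambda,
                      a = if (is.na(a_values[ai])) NULL else a_values[ai],
                      tol = tol, max_sweeps = max_sweeps)
      for (li in seq_len(nl)) {
        f <- fits[[li]]
        if (!f$converged) diverged[li, ai] <- TRUE
        score[li, ai] <- score[li, ai] + ah_loss(f$beta, ss_te) / nfolds
      }
    }
  }
  if (any(diverged)) {
    message(sum(diverged),
            " CV grid point(s) failed to converge and were excluded")
    score[diverged] <- Inf
  }

  # minimizer; ties toward larger lambda, then larger a
  best <- which(score == min(score), arr.ind = TRUE)
  best <- best[order(lambda[best[, 1L]], a_values[best[, 2L]],
                     decreasing = TRUE)[1L], , drop = TRUE]
  sel_lambda <- lambda[best[[1L]]]
  sel_a <- a_values[best[[2L]]]

  full_path <- lapply(a_values, function(av) {
    ah_path(ss_full, penalty, lambda = lambda,
            a = if (is.na(av)) NULL else av,
            tol = tol, max_sweeps = max_sweeps)
  })
  sel_fit <- full_path[[best[[2L]]]][[best[[1L]]]]
  structure(list(lambda = lambda, a_values = a_values, score_grid = score,
                 selected_lambda = sel_lambda, selected_a = sel_a,
                 selected_beta = sel_fit$beta, selected_fit = sel_fit,
                 fold_assignment = fold, seed = seed, penalty = penalty,
                 full_path = full_path, n = n),
            class = "ah_cv")
}

#' @export
print.ah_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of the %s penalty over %d lambda value(s)%s\n",
              max(x$fold_assignment), x$penalty, length(x$lambda),
              if (length(x$a_values) > 1L)
                sprintf(" x %d shape value(s)", length(x$a_values)) else ""))
  cat(sprintf("  selected lambda = %.4g%s; %d nonzero coefficients\n",
              x$selected_lambda,
              if (!is.na(x$selected_a))
                sprintf(", a = %.4g", x$selected_a) else "",
              sum(x$selected_beta != 0)))
  invisible(x)
}

#' Plot a CV score curve
#'
#' CV score against log lambda, one curve per shape value, with the
#' selected point marked.
#'
#' @param x an `"ah_cv"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ah_cv <- function(x, ...) {
  sc <- x$score_grid
  sc[!is.finite(sc)] <- NA
  graphics::matplot(log(x$lambda), sc, type = "l", lty = 1,
                    xlab = expression(log(lambda)), ylab = "CV score",
                    main = sprintf("%s cross-validation", x$penalty), ...)
  graphics::abline(v = log(x$selected_lambda), lty = 2, col = "grey50")
  invisible(x)
}
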