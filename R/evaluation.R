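#' Time grid / value pair for evaluation curves
#'
#' @param times strictly increasing evaluation times.
#' @param values curve values (same length).
#' @param type label, e.g. `"auc"` or `"prediction_error"`.
#' @return an object of class `"eval_curve"`.
#' @export
eval_curve <- function(times, values, type = "curve") {
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 type = type),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("Evaluation curve (%s): %d time point(s)", x$type,
              length(x$times)))
  if (length(x$values)) {
    cat(sprintf(", values in [%.3g, %.3g], median %.3g",
                min(x$values), max(x$values), stats::median(x$values)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.eval_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "s", xlab = "time",
                 ylab = x$type, ...)
  invisible(x)
}

#' Write an evaluation curve as TSV
#'
#' @param curve an [eval_curve()].
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(
    data.frame(time = format(curve$times, digits = 17, trim = TRUE),
               value = format(curve$values, digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Baseline cumulative hazard of a fitted additive hazards model
#'
#' Breslow-type estimator
#' \deqn{\hat\Lambda_0(t) = \int_0^t
#'   \frac{\sum_i dN_i(s) - \sum_i Y_i(s)\,\beta'Z_i\,ds}{\sum_i Y_i(s)},}
#' a right-continuous step (event jumps \eqn{d_k/n_k}) plus piecewise
#' linear drift (slope \eqn{-\overline{\beta'Z}} over the current risk
#' set) between distinct observed times. With \eqn{\beta = 0} and no
#' censoring this is the Nelson-Aalen estimator.
#'
#' @param data the training [survival_dataset()] (covariates on the scale
#'   `beta` was fit on).
#' @param beta coefficient vector.
#' @return an object of class `"ah_cumhaz"`; evaluate it with
#'   [evaluate_cumhaz()] or `predict()`.
#' @export
ah_cumhaz <- function(data, beta) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(beta) != data$p) stop("dimension mismatch", call. = FALSE)
  x <- data$time
  lp <- drop(data$covariates %*% beta)
  u <- sort(unique(x))
  K <- length(u)
  jump <- slope <- numeric(K)
  for (k in seq_len(K)) {
    at_risk <- x >= u[k]
    nk <- sum(at_risk)
    jump[k] <- sum(x == u[k] & data$status == 1) / nk
    slope[k] <- -mean(lp[at_risk])   # drift over (u[k-1], u[k]]
  }
  widths <- diff(c(0, u))
  cum <- cumsum(slope * widths + jump)  # value just after each u[k]
  structure(list(times = u, cum = cum, jump = jump, slope = slope,
                 last_time = max(u)),
            class = "ah_cumhaz")
}

#' Evaluate a baseline cumulative hazard
#'
#' Right-continuous evaluation at arbitrary times; beyond the last
#' at-risk time the curve is extrapolated flat with a warning.
#'
#' @param ch an [ah_cumhaz()] object.
#' @param t evaluation times.
#' @return numeric vector.
#' @export
evaluate_cumhaz <- function(ch, t) {
  stopifnot(inherits(ch, "ah_cumhaz"))
  if (any(t > ch$last_time)) {
    warning("evaluating the baseline cumulative hazard beyond the last ",
            "at-risk time; extrapolating flat")
  }
  k <- findInterval(t, ch$times)          # number of breakpoints <= t
  cum_at <- c(0, ch$cum)[k + 1L]
  left <- c(0, ch$times)[k + 1L]
  # partial drift into the next interval (slope of interval k+1)
  nxt <- pmin(k + 1L, length(ch$times))
  partial <- ifelse(t > left & k < length(ch$times),
                    ch$slope[nxt] * (pmin(t, ch$times[nxt]) - left), 0)
  out <- cum_at + partial
  out[t <= 0] <- 0
  out
}

#' @export
predict.ah_cumhaz <- function(object, times, ...) evaluate_cumhaz(object, times)

#' @export
print.ah_cumhaz <- function(x, ...) {
  cat(sprintf("Baseline cumulative hazard: %d breakpoints on (0, %.3g], final value %.4g\n",
              length(x$times), x$last_time, x$cum[length(x$cum)]))
  invisible(x)
}

#' Predicted survival probabilities under the additive hazards model
#'
#' \eqn{\hat S(t\mid z) = \exp\{-\hat\Lambda_0(t) - (\beta'z)\,t\}},
#' clipped to \eqn{[0, 1]} and forced nonincreasing in t by a running
#' minimum (the additive model does not constrain the estimated
#' conditional hazard to be positive, so the raw curve can locally
#' increase).
#'
#' @param beta coefficient vector.
#' @param cumhaz an [ah_cumhaz()] object fit with the same `beta`.
#' @param z covariate vector, or matrix with samples in rows, on the
#'   same (standardized) scale as training.
#' @param times increasing evaluation times.
#' @return matrix samples x times (a vector if `z` is a single vector).
#' @export
predict_survival <- function(beta, cumhaz, z, times) {
  vec <- is.null(dim(z))
  z <- if (vec) matrix(z, nrow = 1L) else as.matrix(z)
  if (ncol(z) != length(beta)) stop("dimension mismatch", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be increasing", call. = FALSE)
  }
  lp <- drop(z %*% beta)
  ch <- suppressWarnings(evaluate_cumhaz(cumhaz, times))
  S <- exp(-outer(lp, times) - rep(ch, each = nrow(z)))
  S <- pmin(pmax(S, 0), 1)
  if (length(times) > 1L) S <- t(apply(S, 1L, cummin))
  if (vec) drop(S) else S
}

# Kaplan-Meier estimate of the censoring survival G(t) = P(C > t);
# returns right-continuous G and its left limit G(t-).
censor_km <- function(data) {
  km <- survival::survfit(survival::Surv(data$time, 1 - data$status) ~ 1)
  if (length(km$time) == 0L) {
    return(list(G = function(t) rep(1, length(t)),
                Gminus = function(t) rep(1, length(t))))
  }
  right <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  left <- stats::stepfun(km$time, c(1, km$surv), right = TRUE)
  list(G = function(t) right(t), Gminus = function(t) left(t))
}

# IPCW case/control weights at horizon t: cases (event by t) weigh
# 1/G(X_i-), controls (beyond t) weigh 1/G(t); zero where G vanishes.
ipcw_weights <- function(data, t, km = censor_km(data)) {
  case <- data$time <= t & data$status == 1
  control <- data$time > t
  w <- numeric(data$n)
  gi <- km$Gminus(data$time[case])
  w[case] <- ifelse(gi > 0, 1 / gi, 0)
  gt <- km$G(t)
  w[control] <- if (gt > 0) 1 / gt else 0
  list(case = case, control = control, w = w)
}

#' Time-dependent (cumulative/dynamic) AUC under censoring
#'
#' At each horizon t, cases are subjects with an observed event by t and
#' controls those still event-free beyond t; discrimination of the risk
#' marker (higher score = higher risk) is summarized by the weighted
#' probability of concordance, with inverse-probability-of-censoring
#' weights from the Kaplan-Meier estimate of the censoring distribution.
#' Tied marker pairs count 1/2. Horizons with no cases or no controls
#' are dropped with a warning.
#'
#' @param marker per-sample risk score.
#' @param data a [survival_dataset()].
#' @param times evaluation horizons; default the distinct event times
#'   strictly inside the observed follow-up range.
#' @return an [eval_curve()] of AUC(t) values in \[0, 1\].
#' @export
auc_t <- function(marker, data, times = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(marker) != data$n) stop("marker length mismatch", call. = FALSE)
  times <- times %||% {
    et <- sort(unique(data$time[data$status == 1]))
    et[et < max(data$time)]
  }
  km <- censor_km(data)
  keep <- logical(length(times))
  vals <- numeric(length(times))
  for (k in seq_along(times)) {
    wts <- ipcw_weights(data, times[k], km)
    ci <- which(wts$case & wts$w > 0)
    dj <- which(wts$control)
    if (length(ci) == 0L || length(dj) == 0L) next
    mi <- marker[ci]
    mj <- marker[dj]
    wi <- wts$w[ci]
    conc <- vapply(seq_along(mi), function(r) {
      sum((mi[r] > mj) + 0.5 * (mi[r] == mj))
    }, numeric(1L))
    vals[k] <- sum(wi * conc) / (sum(wi) * length(dj))
    keep[k] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " horizon(s) had no cases or no controls and were dropped")
  }
  eval_curve(times[keep], vals[keep], type = "auc")
}

#' Median AUC over the evaluation grid
#'
#' Median of the curve values (midpoint convention for even lengths).
#'
#' @param curve an [eval_curve()].
#' @return scalar.
#' @export
median_auc <- function(curve) {
  stopifnot(inherits(curve, "eval_curve"))
  if (length(curve$values) == 0L) stop("empty evaluation curve", call. = FALSE)
  stats::median(curve$values)
}

#' Brier-type prediction error curve under censoring
#'
#' At each horizon t the squared difference between the observed event
#' state (1 if the event occurred by t, 0 if known event-free) and the
#' predicted event probability \eqn{1 - \hat S_i(t)}, averaged over
#' samples with inverse-probability-of-censoring weights; subjects
#' censored before t contribute through the weighting, not by
#' imputation. A perfect prediction scores 0 everywhere.
#'
#' @param surv_pred matrix of predicted survival probabilities, samples
#'   x `times`, values in \[0, 1\].
#' @param data a [survival_dataset()].
#' @param times evaluation horizons matching `surv_pred` columns.
#' @return an [eval_curve()] of prediction errors.
#' @export
brier_curve <- function(surv_pred, data, times) {
  stopifnot(inherits(data, "survival_dataset"))
  surv_pred <- if (is.null(dim(surv_pred))) {
    matrix(surv_pred, nrow = data$n)
  } else as.matrix(surv_pred)
  if (nrow(surv_pred) != data$n || ncol(surv_pred) != length(times)) {
    stop("'surv_pred' must be samples x times", call. = FALSE)
  }
  if (any(surv_pred < 0 | surv_pred > 1)) {
    stop("survival predictions must lie in [0, 1]", call. = FALSE)
  }
  km <- censor_km(data)
  vals <- vapply(seq_along(times), function(k) {
    wts <- ipcw_weights(data, times[k], km)
    state <- as.numeric(wts$case)
    mean(wts$w * (state - (1 - surv_pred[, k]))^2)
  }, numeric(1L))
  eval_curve(times, vals, type = "prediction_error")
}

# no-information error: every prediction scored against every outcome
noinf_curve <- function(surv_pred, data, times) {
  km <- censor_km(data)
  vals <- vapply(seq_along(times), function(k) {
    wts <- ipcw_weights(data, times[k], km)
    state <- as.numeric(wts$case)
    q <- 1 - surv_pred[, k]
    mean(wts$w * (state^2 - 2 * state * mean(q) + mean(q^2)))
  }, numeric(1L))
  eval_curve(times, vals, type = "no_information_error")
}

#' .632+ weight from the relative overfitting rate
#'
#' \eqn{w(t) = 0.632 / (1 - 0.368\,R(t))}; \eqn{R = 0} gives the classic
#' .632 weight and \eqn{R = 1} full weight on the out-of-sample error.
#'
#' @param R relative overfitting rate(s) in \[0, 1\].
#' @return weight(s) in \[0.632, 1\].
#' @export
w632plus <- function(R) 0.632 / (1 - 0.368 * pmin(pmax(R, 0), 1))

# relative overfitting rate, clipped to [0, 1] and defined as 0 when
# there is no overfitting signal (oob <= app or noinf <= app)
relative_overfit <- function(app, oob, noinf) {
  R <- ifelse(oob > app & noinf > app, (oob - app) / (noinf - app), 0)
  pmin(pmax(R, 0), 1)
}

#' Bootstrap .632+ prediction error curve
#'
#' Combines the apparent (resubstitution) error with an out-of-sample
#' error from B resampled refits. Each replicate draws
#' \eqn{\lfloor 0.632\,n \rfloor} training samples without replacement
#' (so the expected holdout fraction matches the classical out-of-bag
#' fraction); `replace = TRUE` restores classical bootstrap resampling
#' of size n with replacement. The whole training procedure
#' (`fit_procedure`, typically CV + fit) is re-run inside every
#' replicate, so feature selection never leaks into the holdout. The
#' final curve is \eqn{(1-w)\,\mathrm{err}_{app} + w\,
#' \min(\mathrm{err}_{oob}, \gamma)} with \eqn{w} from [w632plus()] and
#' \eqn{\gamma} the no-information error over all prediction/outcome
#' pairings.
#'
#' @param data a [survival_dataset()].
#' @param fit_procedure function taking a training [survival_dataset()]
#'   and returning a prediction function `function(newdata, times)` ->
#'   survival probability matrix.
#' @param times evaluation horizons.
#' @param B number of replicates (default 100).
#' @param seed root seed; replicate draws derive from it.
#' @param replace use classical with-replacement bootstrap resampling.
#' @return an object of class `"ah_err632"`: `curve` (the .632+
#'   [eval_curve()]), `apparent`, `oob`, `noinf` curves, `R`, `w`, `B`,
#'   `seed`, `n_redrawn`.
#' @export
error632plus <- function(data, fit_procedure, times, B = 100L, seed = 1L,
                         replace = FALSE) {
  stopifnot(inherits(data, "survival_dataset"))
  n <- data$n
  pf_full <- fit_procedure(data)
  S_full <- pf_full(data, times)
  apparent <- brier_curve(S_full, data, times)
  noinf <- noinf_curve(S_full, data, times)

  oob_sum <- numeric(length(times))
  oob_cnt <- numeric(length(times))
  n_redrawn <- 0L
  for (r in seq_len(B)) {
    idx <- NULL
    for (attempt in 0:9) {
      cand <- with_seed(derive_seed(seed, 2L, r * 101L + attempt), {
        if (replace) sample.int(n, n, replace = TRUE)
        else sample.int(n, floor(0.632 * n))
      })
      if (sum(data$status[unique(cand)]) >= 2 &&
          length(setdiff(seq_len(n), cand)) > 0L) { idx <- cand; break }
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(idx)) {
      stop("could not draw a training replicate with >= 2 events",
           call. = FALSE)
    }
    hold <- setdiff(seq_len(n), idx)
    train <- subset_dataset(data, idx)
    test <- subset_dataset(data, hold)
    pf <- fit_procedure(train)
    S_ho <- pf(test, times)
    cv <- brier_curve(S_ho, test, times)
    oob_sum <- oob_sum + cv$values
    oob_cnt <- oob_cnt + 1
  }
  oob_vals <- oob_sum / oob_cnt
  Rt <- relative_overfit(apparent$values, oob_vals, noinf$values)
  wt <- w632plus(Rt)
  err <- (1 - wt) * apparent$values + wt * pmin(oob_vals, noinf$values)
  structure(list(curve = eval_curve(times, err, type = "err632plus"),
                 apparent = apparent,
                 oob = eval_curve(times, oob_vals, type = "oob_error"),
                 noinf = noinf, R = Rt, w = wt, B = B, seed = seed,
                 replace = replace, n_redrawn = n_redrawn),
            class = "ah_err632")
}

#' @export
print.ah_err632 <- function(x, ...) {
  cat(sprintf(".632+ prediction error over %d horizon(s), B = %d%s\n",
              length(x$curve$times), x$B,
              if (x$replace) " (with-replacement bootstrap)" else ""))
  cat(sprintf("  median .632+ error %.4g (apparent %.4g, out-of-sample %.4g)\n",
              stats::median(x$curve$values),
              stats::median(x$apparent$values),
              stats::median(x$oob$values)))
  invisible(x)
}

#' Selection stability across resampled refits
#'
#' Repeats the whole tuning-plus-fit pipeline on R random 80%
#' subsamples (drawn without replacement, stratified by event status)
#' and tabulates, for every feature ever selected, the selection
#' frequency, the mean coefficient over the replicates in which it was
#' selected, and the standard error of those coefficients
#' (SD / sqrt(frequency)). Features never selected are omitted. Failed
#' replicates are logged and excluded; the effective denominator is
#' reported.
#'
#' @param data a [survival_dataset()].
#' @param penalty `"lasso"`, `"scad"` or `"sica"`.
#' @param R number of replicates (default 100).
#' @param seed root seed.
#' @param frac subsample fraction (default 0.8).
#' @param nfolds,lambda,nlambda,a_values,tol,max_sweeps passed to
#'   [ah_cv()].
#' @return an object of class `"stability_table"`: a data.frame with
#'   columns `feature`, `frequency`, `mean_coef`, `se_coef`, ordered by
#'   decreasing frequency, with attributes `R` (requested), `R_effective`
#'   (successful replicates) and `seed`.
#' @export
stability_replicates <- function(data, penalty = c("lasso", "scad", "sica"),
                                 R = 100L, seed = 1L, frac = 0.8,
                                 nfolds = 10L, lambda = NULL,
                                 nlambda = 50L, a_values = NULL,
                                 tol = 1e-7, max_sweeps = 10000L) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(data, "survival_dataset"))
  n <- data$n
  p <- data$p
  count <- numeric(p)
  sum_coef <- numeric(p)
  sum_sq <- numeric(p)
  ok <- 0L
  for (r in seq_len(R)) {
    idx <- with_seed(derive_seed(seed, 3L, r), {
      ev <- which(data$status == 1)
      ce <- which(data$status == 0)
      c(sample(ev, floor(frac * length(ev))),
        sample(ce, floor(frac * length(ce))))
    })
    res <- tryCatch({
      sub <- subset_dataset(data, sort(idx))
      cv <- ah_cv(sub, penalty, lambda = lambda, nlambda = nlambda,
                  a_values = a_values, nfolds = min(nfolds, sub$n),
                  seed = derive_seed(seed, 4L, r),
                  tol = tol, max_sweeps = max_sweeps)
      cv$selected_beta
    }, error = function(e) {
      message("stability replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    ok <- ok + 1L
    sel <- res != 0
    count[sel] <- count[sel] + 1
    sum_coef[sel] <- sum_coef[sel] + res[sel]
    sum_sq[sel] <- sum_sq[sel] + res[sel]^2
  }
  keep <- which(count > 0)
  mean_coef <- sum_coef[keep] / count[keep]
  var_coef <- ifelse(count[keep] > 1,
                     pmax(sum_sq[keep] - count[keep] * mean_coef^2, 0) /
                       (count[keep] - 1),
                     NA_real_)
  tab <- data.frame(feature = data$feature_ids[keep],
                    frequency = as.integer(count[keep]),
                    mean_coef = mean_coef,
                    se_coef = sqrt(var_coef / count[keep]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, R = R, R_effective = ok, seed = seed, penalty = penalty,
            class = c("stability_table", "data.frame"))
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("Selection stability (%s): %d feature(s) selected at least once over %d/%d replicates\n",
              attr(x, "penalty"), nrow(x), attr(x, "R_effective"),
              attr(x, "R")))
  print.data.frame(utils::head(x, 20L), row.names = FALSE, digits = 3)
  if (nrow(x) > 20L) cat("  ...", nrow(x) - 20L, "more row(s)\n")
  invisible(x)
}

#' Write a stability table as TSV
#'
#' @param tab a [stability_replicates()] table.
#' @param path output path.
#' @export
write_stability_table <- function(tab, path) {
  out <- data.frame(feature = tab$feature,
                    frequency = tab$frequency,
                    mean_coef = format(tab$mean_coef, digits = 17, trim = TRUE),
                    se_coef = format(tab$se_coef, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
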