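# Default study configuration; any entry can be overridden from the
# config list / YAML file passed to run_study().
default_study_config <- function() {
  list(penalties = c("lasso", "scad", "sica"),
       seed = 1L,
       nfolds = 10L,
       nlambda = 20L,
       lambda_min_ratio = 0.01,
       tol = 1e-4,
       max_sweeps = 500L,
       test_fraction = 0.2,
       n_splits = 1L,
       B = 100L,           # .632+ replicates
       R = 100L,           # stability replicates
       stability_frac = 0.8,
       max_eval_times = 40L,
       refit_in_resample = TRUE,
       use_clinical = TRUE,
       replace = FALSE,
       synthetic = list(),  # ah_sim_config() overrides
       expression = NULL,   # or: paths to input files
       outcomes = NULL,
       orientation = "features_as_rows")
}

read_study_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- default_study_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

# stratified train/test split on event status
split_train_test <- function(status, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (grp in unique(status)) {
      idx <- which(status == grp)
      test <- c(test, sample(idx, round(test_fraction * length(idx))))
    }
    sort(test)
  })
}

# quantile-thinned grid of distinct event times strictly inside the
# observed follow-up range
event_time_grid <- function(data, max_points = 40L) {
  et <- sort(unique(data$time[data$status == 1]))
  et <- et[et < max(data$time)]
  if (length(et) > max_points) {
    et <- unique(stats::quantile(et, probs = seq(0, 1, length.out = max_points),
                                 type = 1L, names = FALSE))
  }
  et
}

# combined raw covariate matrix: genes plus (optionally) the clinical
# block, as one survival_dataset ready for resampling
combine_covariates <- function(data, use_clinical) {
  if (!use_clinical || is.null(data$clinical)) {
    return(list(data = data, clinical_cols = integer(0)))
  }
  comb <- cbind(data$covariates, data$clinical)
  ids <- c(data$feature_ids, colnames(data$clinical))
  ds <- survival_dataset(data$time, data$status, comb, feature_ids = ids,
                         clinical = data$clinical, tau = data$tau)
  list(data = ds,
       clinical_cols = data$p + seq_len(ncol(data$clinical)))
}

# training closure for a penalized genes(+clinical) model: standardizes
# on its own training data, tunes by CV, and returns a survival
# prediction function for new samples
penalized_procedure <- function(penalty, cfg, fixed_lambda = NULL,
                                fixed_a = NULL) {
  force(penalty); force(cfg)
  function(train) {
    std <- standardize_columns(train$covariates)
    tr <- survival_dataset(train$time, train$status, std$x,
                           feature_ids = train$feature_ids, tau = train$tau)
    if (is.null(fixed_lambda)) {
      cv <- ah_cv(tr, penalty,
                  lambda = NULL, a_values = fixed_a,
                  nfolds = min(cfg$nfolds, tr$n),
                  nlambda = cfg$nlambda,
                  lambda_min_ratio = cfg$lambda_min_ratio,
                  seed = derive_seed(cfg$seed, 6L, train$n),
                  tol = cfg$tol %||% 1e-4,
                  max_sweeps = cfg$max_sweeps %||% 500L)
      beta <- cv$selected_beta
    } else {
      ss <- suppressWarnings(ah_suffstats(tr, lowmem = tr$p > 500L))
      grid <- default_lambda_grid(ss, cfg$nlambda, cfg$lambda_min_ratio)
      grid <- sort(unique(c(grid[grid > fixed_lambda], fixed_lambda)),
                   decreasing = TRUE)
      fits <- ah_path(ss, penalty, lambda = grid, a = fixed_a,
                      tol = cfg$tol %||% 1e-4,
                      max_sweeps = cfg$max_sweeps %||% 500L)
      beta <- fits[[length(fits)]]$beta
    }
    ch <- ah_cumhaz(tr, beta)
    function(newdata, times) {
      zstd <- apply_standardization(newdata$covariates, std$center, std$scale)
      predict_survival(beta, ch, zstd, times)
    }
  }
}

# training closure for the clinical-only model (unpenalized fit on the
# standardized clinical block)
clinical_procedure <- function(clinical_cols) {
  force(clinical_cols)
  function(train) {
    zc <- train$covariates[, clinical_cols, drop = FALSE]
    std <- standardize_columns(zc)
    tr <- survival_dataset(train$time, train$status, std$x, tau = train$tau)
    beta <- ah_lsfit(suppressWarnings(ah_suffstats(tr)))
    ch <- ah_cumhaz(tr, beta)
    function(newdata, times) {
      zstd <- apply_standardization(
        newdata$covariates[, clinical_cols, drop = FALSE],
        std$center, std$scale)
      predict_survival(beta, ch, zstd, times)
    }
  }
}

#' Run the full comparative study
#'
#' Orchestrates the study design end-to-end on either synthetic data or
#' user-supplied expression/outcome files: a stratified 80/20
#' train/test split with training-only standardization; CV-tuned lasso,
#' SCAD and SICA fits whose test-set risk scores are evaluated by
#' time-dependent AUC (against a clinical-only baseline); bootstrap
#' .632+ prediction error curves for the clinical-only model and each
#' penalized model (the entire selection pipeline is re-fit inside
#' every resample unless `refit_in_resample = FALSE`); and selection
#' stability tables over resampled refits. All tables and curves are
#' written to `out_dir` together with the configuration, seeds and
#' package version.
#'
#' @param config a named list or path to a YAML file; see the package
#'   vignette for the accepted keys (penalties, seed, nfolds, nlambda,
#'   test_fraction, B, R, synthetic block or expression/outcomes paths,
#'   ...).
#' @param out_dir report directory (created).
#' @return an object of class `"ah_study"` with components `config`,
#'   `data`, `split`, `cv` (per penalty), `markers`, `auc` (curves and
#'   medians, including the clinical-only baseline), `err632` (per
#'   model), `stability` (per penalty), `files`.
#' @export
run_study <- function(config = list(), out_dir = tempfile("ah_study_")) {
  cfg <- read_study_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- data ----
  if (!is.null(cfg$expression)) {
    ft <- read_expression(cfg$expression, orientation = cfg$orientation)
    outcomes <- read_outcomes(cfg$outcomes)
    raw <- assemble_dataset(ft, outcomes, standardize = FALSE)
    truth <- NULL
  } else {
    sim_args <- cfg$synthetic
    sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, 7L)
    sim <- ah_simulate(do.call(ah_sim_config, sim_args))
    raw <- sim$data
    truth <- sim$truth
  }
  comb <- combine_covariates(raw, cfg$use_clinical)
  full <- comb$data
  clinical_cols <- comb$clinical_cols
  penalties <- cfg$penalties

  # ---- split and training-only standardization ----
  test_idx <- split_train_test(full$status, cfg$test_fraction,
                               derive_seed(cfg$seed, 8L))
  train_raw <- subset_dataset(full, setdiff(seq_len(full$n), test_idx))
  test_raw <- subset_dataset(full, test_idx)
  std <- standardize_columns(train_raw$covariates)
  train <- survival_dataset(train_raw$time, train_raw$status, std$x,
                            feature_ids = full$feature_ids,
                            tau = train_raw$tau)
  ztest <- apply_standardization(test_raw$covariates, std$center, std$scale)

  # ---- per-penalty CV fits and test-set AUC ----
  cvs <- list()
  markers <- list()
  auc_curves <- list()
  medians <- c()
  test_times <- sort(unique(test_raw$time[test_raw$status == 1]))
  test_times <- test_times[test_times < max(test_raw$time)]
  for (pen in penalties) {
    cv <- ah_cv(train, pen, nfolds = min(cfg$nfolds, train$n),
                lambda = NULL, nlambda = cfg$nlambda,
                lambda_min_ratio = cfg$lambda_min_ratio, tol = cfg$tol,
                max_sweeps = cfg$max_sweeps,
                seed = derive_seed(cfg$seed, 9L, match(pen, penalties)))
    cvs[[pen]] <- cv
    markers[[pen]] <- drop(ztest %*% cv$selected_beta)
    auc_curves[[pen]] <- auc_t(markers[[pen]], test_raw, test_times)
    medians[pen] <- median_auc(auc_curves[[pen]])
  }
  if (length(clinical_cols)) {
    zc_tr <- train$covariates[, clinical_cols, drop = FALSE]
    beta_c <- ah_lsfit(suppressWarnings(ah_suffstats(
      survival_dataset(train$time, train$status, zc_tr, tau = train$tau))))
    markers[["clinical"]] <- drop(ztest[, clinical_cols, drop = FALSE] %*% beta_c)
    auc_curves[["clinical"]] <- auc_t(markers[["clinical"]], test_raw,
                                      test_times)
    medians["clinical"] <- median_auc(auc_curves[["clinical"]])
  }

  # ---- .632+ prediction error curves on the full data ----
  eval_times <- event_time_grid(full, cfg$max_eval_times)
  err632 <- list()
  if (length(clinical_cols)) {
    err632[["clinical"]] <- error632plus(full, clinical_procedure(clinical_cols),
                                         eval_times, B = cfg$B,
                                         seed = derive_seed(cfg$seed, 10L),
                                         replace = cfg$replace)
  }
  for (pen in penalties) {
    if (!cfg$refit_in_resample) {
      warning("refit_in_resample = FALSE: penalty tuning is NOT re-run ",
              "inside bootstrap training sets; out-of-sample error will be ",
              "biased downward", immediate. = TRUE)
      proc <- penalized_procedure(pen, cfg,
                                  fixed_lambda = cvs[[pen]]$selected_lambda,
                                  fixed_a = cvs[[pen]]$selected_a)
    } else {
      proc <- penalized_procedure(pen, cfg)
    }
    err632[[pen]] <- error632plus(full, proc, eval_times, B = cfg$B,
                                  seed = derive_seed(cfg$seed, 11L,
                                                     match(pen, penalties)),
                                  replace = cfg$replace)
  }

  # ---- stability tables on the full data ----
  stability <- list()
  for (pen in penalties) {
    stability[[pen]] <- stability_replicates(
      full, pen, R = cfg$R, frac = cfg$stability_frac,
      nfolds = cfg$nfolds, nlambda = cfg$nlambda, tol = cfg$tol,
      max_sweeps = cfg$max_sweeps,
      seed = derive_seed(cfg$seed, 12L, match(pen, penalties)))
  }

  # ---- report ----
  files <- c()
  for (pen in names(auc_curves)) {
    f <- file.path(out_dir, sprintf("auc_%s.tsv", pen))
    write_curve(auc_curves[[pen]], f)
    files <- c(files, f)
  }
  for (nm in names(err632)) {
    f <- file.path(out_dir, sprintf("err632_%s.tsv", nm))
    write_curve(err632[[nm]]$curve, f)
    files <- c(files, f)
  }
  for (pen in names(stability)) {
    f <- file.path(out_dir, sprintf("stability_%s.tsv", pen))
    write_stability_table(stability[[pen]], f)
    files <- c(files, f)
  }
  for (pen in penalties) {
    beta <- cvs[[pen]]$selected_beta
    sel <- beta != 0
    f <- file.path(out_dir, sprintf("coefficients_%s.tsv", pen))
    utils::write.table(
      data.frame(feature = full$feature_ids[sel],
                 coefficient = format(beta[sel], digits = 17, trim = TRUE)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  report <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("ahpen"))),
    sprintf("seed\t%d", cfg$seed),
    sprintf("n\t%d", full$n),
    sprintf("p\t%d", full$p),
    sprintf("events\t%d", sum(full$status)),
    sprintf("n_train\t%d", train$n),
    sprintf("n_test\t%d", test_raw$n),
    sprintf("median_auc_%s\t%s", names(medians),
            format(medians, digits = 17, trim = TRUE)),
    sprintf("median_err632_%s\t%s", names(err632),
            vapply(err632, function(e)
              format(stats::median(e$curve$values), digits = 17,
                     trim = TRUE), character(1L))),
    sprintf("n_selected_%s\t%d", penalties,
            vapply(penalties, function(pen)
              sum(cvs[[pen]]$selected_beta != 0), integer(1L))),
    sprintf("selected_lambda_%s\t%s", penalties,
            vapply(penalties, function(pen)
              format(cvs[[pen]]$selected_lambda, digits = 17, trim = TRUE),
              character(1L))))
  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)
  files <- c(files, cfg_path, report_path)

  structure(list(config = cfg, data = full, truth = truth,
                 split = list(test = test_idx,
                              center = std$center, scale = std$scale),
                 cv = cvs, markers = markers,
                 auc = list(curves = auc_curves, median = medians),
                 err632 = err632, stability = stability,
                 out_dir = out_dir, files = files),
            class = "ah_study")
}

#' @export
print.ah_study <- function(x, ...) {
  cat("Additive hazards comparative study\n")
  cat(sprintf("  n = %d, p = %d, penalties: %s\n", x$data$n, x$data$p,
              paste(x$config$penalties, collapse = ", ")))
  cat("  median AUC(t) on the held-out split:\n")
  for (nm in names(x$auc$median)) {
    cat(sprintf("    %-10s %.3f\n", nm, x$auc$median[nm]))
  }
  cat("  median .632+ prediction error:\n")
  for (nm in names(x$err632)) {
    cat(sprintf("    %-10s %.4f\n", nm,
                stats::median(x$err632[[nm]]$curve$values)))
  }
  cat(sprintf("  report written to %s\n", x$out_dir))
  invisible(x)
}

#' Rank single features by median time-dependent AUC
#'
#' Scores each candidate feature as a one-dimensional risk marker via
#' [auc_t()] + [median_auc()] and returns the top k, together with the
#' sign of association from the univariate unpenalized additive hazards
#' coefficient \eqn{b_j / V_{jj}}.
#'
#' @param data a [survival_dataset()].
#' @param features feature ids or column indices to score (default all).
#' @param times AUC horizons (default: distinct event times inside the
#'   follow-up range).
#' @param k number of top features to return (default 5; `k = 0` gives
#'   an empty table).
#' @return data.frame `feature`, `median_auc`, `coefficient`, `sign`,
#'   ordered by decreasing median AUC.
#' @export
top_features_by_auc <- function(data, features = NULL, times = NULL, k = 5L) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(features)) {
    cols <- seq_len(data$p)
  } else if (is.character(features)) {
    cols <- match(features, data$feature_ids)
    if (anyNA(cols)) stop("unknown feature id(s): ",
                          paste(features[is.na(cols)], collapse = ", "),
                          call. = FALSE)
  } else {
    cols <- as.integer(features)
  }
  if (k > length(cols)) stop("'k' exceeds the number of candidate features",
                             call. = FALSE)
  if (k == 0L) {
    return(data.frame(feature = character(0), median_auc = numeric(0),
                      coefficient = numeric(0), sign = numeric(0)))
  }
  ss <- ah_suffstats(data)
  med <- vapply(cols, function(j) {
    median_auc(suppressWarnings(auc_t(data$covariates[, j], data, times)))
  }, numeric(1L))
  coefs <- ifelse(ss$Vdiag[cols] > 0, ss$b[cols] / ss$Vdiag[cols], 0)
  ord <- order(med, decreasing = TRUE)[seq_len(k)]
  data.frame(feature = data$feature_ids[cols][ord],
             median_auc = med[ord],
             coefficient = coefs[ord],
             sign = sign(coefs[ord]),
             row.names = NULL)
}
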