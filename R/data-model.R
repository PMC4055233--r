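#' Construct a validated right-censored survival dataset
#'
#' Bundles observed follow-up times \eqn{X_i = \min(T_i, C_i)}, event
#' indicators \eqn{\Delta_i = I(T_i \le C_i)} and a baseline covariate matrix
#' \eqn{Z} into the container every downstream routine in the package
#' consumes. Optional clinical covariates are carried alongside the
#' high-dimensional block, and `tau` fixes the horizon over which
#' risk-set integrals are taken.
#'
#' @param time positive follow-up times, one per sample.
#' @param status event indicators, 0 = censored, 1 = event.
#' @param covariates numeric matrix, samples in rows.
#' @param feature_ids optional column labels; defaults to existing colnames
#'   or `"f1"..."fp"`.
#' @param clinical optional numeric matrix of clinical covariates with the
#'   same number of rows, with column labels.
#' @param tau integration horizon; defaults to `max(time)`. Values beyond
#'   the largest observed time are allowed (the risk set is then empty and
#'   integration stops at the last observed time).
#' @return an object of class `"survival_dataset"` with components
#'   `time`, `status`, `covariates`, `feature_ids`, `clinical`, `tau`, `n`,
#'   `p`.
#' @export
survival_dataset <- function(time, status, covariates, feature_ids = NULL,
                             clinical = NULL, tau = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(time)
  if (length(status) != n) {
    stop("'time' and 'status' must have the same length", call. = FALSE)
  }
  if (nrow(covariates) != n) {
    stop(sprintf("covariate matrix has %d rows but there are %d samples",
                 nrow(covariates), n), call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("all follow-up times must be finite (no missing values)", call. = FALSE)
  }
  if (any(time <= 0)) {
    stop("all follow-up times must be > 0", call. = FALSE)
  }
  if (anyNA(status) || !all(status %in% c(0, 1))) {
    stop("'status' must be 0/1 with no missing values", call. = FALSE)
  }
  if (anyNA(covariates) || any(!is.finite(covariates))) {
    stop("covariates must be finite with no missing values", call. = FALSE)
  }
  p <- ncol(covariates)
  feature_ids <- feature_ids %||% colnames(covariates) %||%
    paste0("f", seq_len(p))
  if (length(feature_ids) != p) {
    stop("'feature_ids' length must match the number of covariate columns",
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(covariates) <- feature_ids
  if (!is.null(clinical)) {
    clinical <- as.matrix(clinical)
    storage.mode(clinical) <- "double"
    if (nrow(clinical) != n) {
      stop("clinical matrix must have one row per sample", call. = FALSE)
    }
    if (anyNA(clinical) || any(!is.finite(clinical))) {
      stop("clinical covariates must be finite with no missing values",
           call. = FALSE)
    }
    if (is.null(colnames(clinical))) {
      colnames(clinical) <- paste0("clin", seq_len(ncol(clinical)))
    }
  }
  tau <- tau %||% max(time)
  stopifnot_scalar(tau, "tau", positive = TRUE)
  if (tau < min(time)) {
    stop("'tau' is smaller than the earliest observed time", call. = FALSE)
  }
  structure(list(time = time, status = status, covariates = covariates,
                 feature_ids = as.character(feature_ids),
                 clinical = clinical, tau = tau, n = n, p = p),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: n = %d samples, p = %d covariates\n",
              x$n, x$p))
  cat(sprintf("  events: %d (%.1f%%), follow-up range [%.3g, %.3g], tau = %.3g\n",
              sum(x$status), 100 * mean(x$status),
              min(x$time), max(x$time), x$tau))
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical covariates: %s\n",
                paste(colnames(x$clinical), collapse = ", ")))
  }
  invisible(x)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects the GEO series-matrix layout by default: features in rows,
#' first column feature ids, first row sample ids. Set
#' `orientation = "samples_as_rows"` for the transposed layout.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`.
#' @return an object of class `"feature_table"`: a list with `matrix`
#'   (samples x features), `sample_ids`, `feature_ids` and a logical
#'   `zero_variance` flag per feature (flagged, never dropped).
#' @export
read_expression <- function(path,
                            orientation = c("features_as_rows",
                                            "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      row.names = NULL, check.names = FALSE,
                      colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("parse error: '", path,
         "' does not contain a header row plus at least one data row/column",
         call. = FALSE)
  }
  row_ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  col_ids <- colnames(body)
  mat <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & nzchar(body[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))
      stop(sprintf("parse error in '%s': non-numeric value '%s' at row '%s', column '%s'",
                   path, body[[j]][bad[1L]], row_ids[bad[1L]], col_ids[j]),
           call. = FALSE)
    }
    mat[, j] <- v
  }
  if (orientation == "features_as_rows") {
    feature_ids <- row_ids
    sample_ids <- col_ids
    mat <- t(mat)
  } else {
    feature_ids <- col_ids
    sample_ids <- row_ids
  }
  feature_table(mat, sample_ids = sample_ids, feature_ids = feature_ids)
}

#' Construct a feature table
#'
#' @param matrix numeric matrix, samples in rows.
#' @param sample_ids,feature_ids unique identifiers.
#' @return a `"feature_table"` object.
#' @export
feature_table <- function(matrix, sample_ids, feature_ids) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != length(sample_ids)) {
    stop("sample ids do not match matrix rows", call. = FALSE)
  }
  if (ncol(matrix) != length(feature_ids)) {
    stop("feature ids do not match matrix columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(matrix) <- list(sample_ids, feature_ids)
  zero_var <- apply(matrix, 2L, function(col) stats::var(col) == 0 || length(col) == 1L)
  structure(list(matrix = matrix,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 zero_variance = unname(zero_var)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features (%d zero-variance)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$zero_variance)))
  invisible(x)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()] under the features-as-rows layout;
#' numeric values are written with full precision so a read/write/read
#' round trip reproduces the matrix bit-exactly for finite decimal input.
#'
#' @param ft a `"feature_table"`.
#' @param path output path.
#' @export
write_expression <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  m <- t(ft$matrix)  # features as rows
  df <- data.frame(feature_id = rownames(m),
                   apply(m, 2L, function(col) format(col, digits = 17, trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an outcome table
#'
#' CSV with a header; required columns `sample_id`, `time`, `status`; any
#' further numeric columns are treated as clinical covariates.
#'
#' @param path path to a CSV file.
#' @return a data.frame.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "status")
  missing_cols <- setdiff(need, colnames(out))
  if (length(missing_cols)) {
    stop("outcome table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write an outcome table as CSV
#'
#' @param outcomes data.frame with `sample_id`, `time`, `status` and
#'   optional clinical columns.
#' @param path output path.
#' @export
write_outcomes <- function(outcomes, path) {
  num <- vapply(outcomes, is.numeric, logical(1L))
  out <- outcomes
  out[num] <- lapply(out[num], function(col) format(col, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join expression features with outcomes into a survival dataset
#'
#' Samples are matched by id; every outcome sample must be present in the
#' feature table. With `standardize = TRUE` (the default, since penalized
#' fits are scale-sensitive) each covariate column is centered and scaled
#' to unit sample standard deviation; constant columns are centered to 0
#' and their scale left at 1. The applied centers and scales are stored in
#' attributes `"center"` and `"scale"` for use on new samples.
#'
#' @param features a `"feature_table"`.
#' @param outcomes data.frame as returned by [read_outcomes()].
#' @param standardize center/scale covariate columns (default `TRUE`).
#' @param tau optional integration horizon.
#' @return a `"survival_dataset"`; clinical columns from `outcomes` are
#'   carried unstandardized in `$clinical`.
#' @export
assemble_dataset <- function(features, outcomes, standardize = TRUE,
                             tau = NULL) {
  stopifnot(inherits(features, "feature_table"))
  ids <- as.character(outcomes$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in outcomes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(ids, features$sample_ids)
  if (length(unknown)) {
    stop("outcome sample id(s) not present in the feature table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  Z <- features$matrix[match(ids, features$sample_ids), , drop = FALSE]
  time <- as.numeric(outcomes$time)
  status <- as.numeric(outcomes$status)
  if (anyNA(time) || any(time <= 0)) {
    stop("outcome times must be positive with no missing values",
         call. = FALSE)
  }
  clin_cols <- setdiff(colnames(outcomes), c("sample_id", "time", "status"))
  clinical <- NULL
  if (length(clin_cols)) {
    clinical <- as.matrix(outcomes[, clin_cols, drop = FALSE])
    storage.mode(clinical) <- "double"
    rownames(clinical) <- ids
  }
  center <- rep(0, ncol(Z))
  scale <- rep(1, ncol(Z))
  if (standardize) {
    std <- standardize_columns(Z)
    Z <- std$x
    center <- std$center
    scale <- std$scale
  }
  rownames(Z) <- ids
  ds <- survival_dataset(time, status, Z, feature_ids = features$feature_ids,
                         clinical = clinical, tau = tau)
  attr(ds, "center") <- center
  attr(ds, "scale") <- scale
  attr(ds, "standardized") <- standardize
  ds
}

# Center all columns; scale non-constant columns to unit sample SD.
# Returns the transformed matrix plus the applied centers/scales.
standardize_columns <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  sds <- apply(xc, 2L, stats::sd)
  scale <- ifelse(is.na(sds) | sds == 0, 1, sds)
  list(x = sweep(xc, 2L, scale, "/"), center = center, scale = scale)
}

# Apply stored training centers/scales to new covariate rows.
apply_standardization <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

# Row subset of a survival_dataset, preserving tau and standardization
# attributes (used by CV folds and resampling).
subset_dataset <- function(data, idx, tau = data$tau) {
  ds <- survival_dataset(data$time[idx], data$status[idx],
                         data$covariates[idx, , drop = FALSE],
                         feature_ids = data$feature_ids,
                         clinical = if (!is.null(data$clinical))
                           data$clinical[idx, , drop = FALSE] else NULL,
                         tau = tau)
  attr(ds, "center") <- attr(data, "center")
  attr(ds, "scale") <- attr(data, "scale")
  attr(ds, "standardized") <- attr(data, "standardized")
  ds
}
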