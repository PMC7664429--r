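#' Coefficient of variation
#'
#' Sample standard deviation divided by the arithmetic mean — a scale-free
#' variability measure. Negative when the mean is negative; callers compare
#' its absolute value against a threshold.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return The CV (can be negative).
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("coefficient_of_variation: need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0)
    stop("coefficient_of_variation: undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Drop low-variability features by coefficient of variation
#'
#' A feature is kept when `|CV| >= threshold` across participants (a tie at
#' the threshold keeps). Features with zero mean have undefined CV and are
#' rejected.
#'
#' @param matrix Participants-by-features numeric matrix.
#' @param threshold CV threshold as a fraction (default 0.5, i.e. 50%
#'   variability).
#' @return List: `matrix` (kept columns), `report` (data.frame with per-
#'   feature `cv`, `kept`, `reason`), `threshold`.
#' @export
cv_filter <- function(matrix, threshold = 0.5) {
  if (is.null(dim(matrix)) || nrow(matrix) < 2L)
    stop("cv_filter: need a matrix with at least 2 participants", call. = FALSE)
  cv <- vapply(seq_len(ncol(matrix)), function(j) {
    col <- matrix[, j]
    if (mean(col) == 0) NA_real_ else stats::sd(col) / mean(col)
  }, numeric(1))
  kept <- !is.na(cv) & abs(cv) >= threshold
  report <- data.frame(feature = colnames(matrix), cv = cv, kept = kept,
                       reason = ifelse(kept, "kept", "cv_reject"),
                       stringsAsFactors = FALSE)
  if (!any(kept))
    stop("cv_filter: every feature rejected — lower the threshold", call. = FALSE)
  out <- matrix[, kept, drop = FALSE]
  attr(out, "exercise_id") <- attr(matrix, "exercise_id")
  list(matrix = out, report = report, threshold = threshold)
}

#' Univariate within-cluster sum of squares for k clusters
#'
#' Minimal over all partitions of the values into `k` groups of
#' `sum((x - group mean)^2)`. In one dimension the optimum is attained by a
#' contiguous partition of the sorted values, found here by dynamic
#' programming (exact, deterministic).
#'
#' @param values Numeric vector, length >= k.
#' @param k Number of clusters (default 2, as used for feature scoring).
#' @return The minimal WCSS.
#' @export
wcss_1d <- function(values, k = 2L) {
  x <- sort(as.numeric(values))
  n <- length(x)
  k <- as.integer(k)
  if (n < k)
    stop(sprintf("wcss_1d: %d values cannot form %d clusters", n, k), call. = FALSE)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # sse of the contiguous block (i..j] in prefix-sum terms, 0-based prefixes
  sse <- function(i, j) {
    s <- cs[j] - if (i > 0) cs[i] else 0
    s2 <- cs2[j] - if (i > 0) cs2[i] else 0
    s2 - s^2 / (j - i)
  }
  dp <- rep(Inf, n + 1L)
  dp[1L] <- 0
  for (g in seq_len(k)) {
    ndp <- rep(Inf, n + 1L)
    for (j in g:n) {                 # j points can hold at most j clusters
      best <- Inf
      for (i in (g - 1L):(j - 1L)) {
        if (is.finite(dp[i + 1L])) {
          v <- dp[i + 1L] + sse(i, j)
          if (v < best) best <- v
        }
      }
      ndp[j + 1L] <- best
    }
    dp <- ndp
  }
  max(dp[n + 1L], 0)
}

#' Keep the most class-separable features by univariate WCSS
#'
#' Scores every feature column with the two-cluster [wcss_1d()] on its raw
#' (unstandardized) values and keeps either those at or below an explicit
#' threshold, or the `top_k` smallest.
#'
#' @param matrix Participants-by-features numeric matrix.
#' @param threshold Keep features with `wcss <= threshold` (exclusive with
#'   `top_k`).
#' @param top_k Keep the `top_k` features of smallest WCSS.
#' @param k Number of clusters assumed when scoring (default 2).
#' @return List: `matrix`, `report` (per-feature `wcss`, `kept`, `reason`),
#'   and the rule used.
#' @export
wcss_filter <- function(matrix, threshold = NULL, top_k = NULL, k = 2L) {
  if (is.null(threshold) == is.null(top_k))
    stop("wcss_filter: give exactly one of threshold or top_k", call. = FALSE)
  if (!is.null(threshold) && threshold <= 0)
    stop("wcss_filter: threshold must be > 0", call. = FALSE)
  w <- vapply(seq_len(ncol(matrix)), function(j) wcss_1d(matrix[, j], k),
              numeric(1))
  if (!is.null(threshold)) {
    kept <- w <= threshold
  } else {
    top_k <- min(as.integer(top_k), ncol(matrix))
    kept <- rank(w, ties.method = "first") <= top_k
  }
  report <- data.frame(feature = colnames(matrix), wcss = w, kept = kept,
                       reason = ifelse(kept, "kept", "wcss_reject"),
                       stringsAsFactors = FALSE)
  if (!any(kept))
    stop("wcss_filter: every feature rejected — raise the threshold", call. = FALSE)
  out <- matrix[, kept, drop = FALSE]
  attr(out, "exercise_id") <- attr(matrix, "exercise_id")
  list(matrix = out, report = report, threshold = threshold, top_k = top_k)
}

#' Contextual feature subsets
#'
#' Three domain groupings of the canonical features used to probe which kind
#' of information drives the clustering: `statistical` (dispersion/shape),
#' `signal` (event and level), `error` (higher moments and information
#' content).
#'
#' @param matrix Participants-by-features numeric matrix.
#' @param set_id One of `"statistical"`, `"signal"`, `"error"`.
#' @return Column subset of `matrix`.
#' @export
contextual_set <- function(matrix, set_id = c("statistical", "signal", "error")) {
  set_id <- match.arg(set_id)
  wanted <- switch(set_id,
    statistical = c("standard_deviation", "quartile_deviation", "skewness",
                    "kurtosis", "reg_slope"),
    signal = c("n_gsr", "gsr_energy", "minimum", "total_sum"),
    error = c("moment4", "moment5", "rms", "entropy"))
  missing <- setdiff(wanted, colnames(matrix))
  if (length(missing))
    stop(sprintf("contextual_set('%s'): missing feature(s): %s",
                 set_id, paste(missing, collapse = ", ")), call. = FALSE)
  out <- matrix[, wanted, drop = FALSE]
  attr(out, "exercise_id") <- attr(matrix, "exercise_id")
  out
}

#' Published per-exercise feature presets
#'
#' Fixed feature subsets reported for each exercise, for users who want the
#' published selections instead of the data-driven CV+WCSS reduction. The
#' Exercise-3 list's "energy of signal" is read as the GSR energy already in
#' the subset, and "root of the mean square error" as the signal `rms`.
#'
#' @param matrix Participants-by-features numeric matrix.
#' @param preset One of `"paper_ex1"`, `"paper_ex2"`, `"paper_ex3"`.
#' @return Column subset of `matrix`.
#' @export
preset_features <- function(matrix, preset = c("paper_ex1", "paper_ex2", "paper_ex3")) {
  preset <- match.arg(preset)
  wanted <- switch(preset,
    paper_ex1 = c("standard_deviation", "reg_slope", "n_gsr", "total_sum"),
    paper_ex2 = c("standard_deviation", "quartile_deviation", "reg_slope",
                  "gsr_energy", "minimum", "moment4", "moment5", "skewness",
                  "rms", "entropy"),
    paper_ex3 = c("standard_deviation", "quartile_deviation", "reg_slope",
                  "n_gsr", "gsr_energy", "minimum", "moment4", "moment5",
                  "skewness", "kurtosis", "rms", "entropy"))
  missing <- setdiff(wanted, colnames(matrix))
  if (length(missing))
    stop(sprintf("preset_features('%s'): missing feature(s): %s",
                 preset, paste(missing, collapse = ", ")), call. = FALSE)
  out <- matrix[, wanted, drop = FALSE]
  attr(out, "exercise_id") <- attr(matrix, "exercise_id")
  out
}

#' PCA transform keeping every component
#'
#' Rotates the (optionally standardized) feature matrix into its principal
#' axes while maintaining the number of variables: the output has exactly as
#' many columns as the input, ordered by decreasing explained variance, and
#' total variance is conserved. Implemented by eigendecomposition of the
#' covariance of the centered/scaled data so that all p components are
#' returned even when p exceeds the participant count. Constant columns are
#' dropped with a warning when standardizing.
#'
#' @param matrix Participants-by-features numeric matrix, >= 2 rows.
#' @param standardize Scale columns to unit variance first (default TRUE).
#' @return Score matrix (same rownames, columns `PC1..PCp`) with attributes
#'   `sdev` (component standard deviations) and `rotation`.
#' @export
pca_transform <- function(matrix, standardize = TRUE) {
  if (is.null(dim(matrix)) || nrow(matrix) < 2L)
    stop("pca_transform: need at least 2 participants", call. = FALSE)
  if (standardize) {
    sds <- apply(matrix, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("pca_transform: dropping constant column(s): %s",
                      paste(colnames(matrix)[sds == 0], collapse = ", ")),
              call. = FALSE)
      matrix <- matrix[, sds > 0, drop = FALSE]
    }
  }
  z <- scale(matrix, center = TRUE, scale = standardize)
  e <- eigen(stats::cov(z), symmetric = TRUE)
  vec <- e$vectors
  # deterministic sign: largest-|loading| entry of each axis is positive
  for (j in seq_len(ncol(vec))) {
    piv <- which.max(abs(vec[, j]))
    if (vec[piv, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- z %*% vec
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(matrix)
  structure(scores,
            sdev = sqrt(pmax(e$values, 0)),
            rotation = vec,
            exercise_id = attr(matrix, "exercise_id"))
}
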