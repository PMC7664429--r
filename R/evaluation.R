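#' Confusion counts between predicted and reference binary labels
#'
#' Label 1 is the positive class. Participants are aligned by id; both
#' tables must cover exactly the same set.
#'
#' @param predicted,reference [label_table()]s over identical participants.
#' @return Named list `tp`, `fn`, `tn`, `fp` (sums to the participant
#'   count).
#' @export
confusion <- function(predicted, reference) {
  if (!setequal(names(predicted), names(reference)))
    stop("confusion: participant sets differ", call. = FALSE)
  p <- as.integer(predicted[names(reference)])
  r <- as.integer(reference)
  list(tp = sum(p == 1L & r == 1L),
       fn = sum(p == 0L & r == 1L),
       tn = sum(p == 0L & r == 0L),
       fp = sum(p == 1L & r == 0L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `acc = (tp + tn) / n`, `tpr = tp / (tp + fn)` (sensitivity),
#' `tnr = tn / (tn + fp)` (specificity). A metric whose margin is empty is
#' reported as `NA` rather than coerced to 0, so degenerate clusterings
#' stay visible.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Named list `acc`, `tpr`, `tnr`.
#' @export
eval_metrics <- function(counts) {
  n <- counts$tp + counts$fn + counts$tn + counts$fp
  if (n == 0L)
    stop("eval_metrics: empty confusion table", call. = FALSE)
  list(acc = (counts$tp + counts$tn) / n,
       tpr = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_,
       tnr = if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_)
}

eval_report_row <- function(method, feature_set, pca, counts, metrics, reference) {
  data.frame(method = method, feature_set = feature_set, pca = pca,
             n = counts$tp + counts$fn + counts$tn + counts$fp,
             tp = counts$tp, fn = counts$fn, tn = counts$tn, fp = counts$fp,
             acc = metrics$acc, tpr = metrics$tpr, tnr = metrics$tnr,
             reference = reference, stringsAsFactors = FALSE)
}

#' Run the full clustering-vs-reference evaluation grid
#'
#' For every combination of clustering method (three hierarchical distance
#' variants and k-means), PCA on/off, and feature set, participants are
#' partitioned into two classes and the partition is scored against the
#' JAWS-derived reference (and, when supplied, against the expert labels).
#'
#' @param features Participants-by-features numeric matrix.
#' @param jaws_labels Reference [label_table()] (questionnaire-derived).
#' @param expert_labels Optional expert [label_table()].
#' @param methods Methods to run; default all four.
#' @param feature_sets Named list of feature matrices to evaluate; default
#'   `list(all = features)`. Use [contextual_set()] to build entries.
#' @param pca Logical vector of PCA settings to cross (default both).
#' @param polarity `"best_match"` (default) or `"fixed"`, see
#'   [assign_polarity()].
#' @param seed Seed forwarded to k-means.
#' @return data.frame, one row per (method, feature set, pca, reference)
#'   combination, with confusion counts and `acc`/`tpr`/`tnr`.
#' @export
evaluate_pipeline <- function(features, jaws_labels, expert_labels = NULL,
                              methods = c("tree_euclidean", "tree_spearman",
                                          "tree_correlation", "kmeans"),
                              feature_sets = NULL, pca = c(FALSE, TRUE),
                              polarity = c("best_match", "fixed"),
                              seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(feature_sets)) feature_sets <- list(all = features)
  if (!setequal(rownames(features), names(jaws_labels)))
    stop("evaluate_pipeline: feature matrix and JAWS labels cover different participants",
         call. = FALSE)
  refs <- list(jaws = jaws_labels)
  if (!is.null(expert_labels)) refs$expert <- expert_labels
  rows <- list()
  for (set_name in names(feature_sets)) {
    for (use_pca in pca) {
      m <- feature_sets[[set_name]]
      if (use_pca) m <- suppressWarnings(pca_transform(m))
      for (method in methods) {
        result <- tryCatch({
          if (method == "kmeans") {
            kmeans_two_clusters(m, seed = seed)
          } else {
            metric <- sub("^tree_", "", method)
            hierarchical_two_clusters(m, metric = metric)
          }
        }, error = function(e) e)
        for (ref_name in names(refs)) {
          if (inherits(result, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              method = method, feature_set = set_name, pca = use_pca,
              n = NA_integer_, tp = NA_integer_, fn = NA_integer_,
              tn = NA_integer_, fp = NA_integer_, acc = NA_real_,
              tpr = NA_real_, tnr = NA_real_, reference = ref_name,
              stringsAsFactors = FALSE)
            next
          }
          aligned <- assign_polarity(result, refs[[ref_name]], polarity)
          cc <- confusion(aligned$labels, refs[[ref_name]])
          rows[[length(rows) + 1L]] <-
            eval_report_row(method, set_name, use_pca, cc, eval_metrics(cc),
                            ref_name)
        }
      }
    }
  }
  do.call(rbind, rows)
}
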