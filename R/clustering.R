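#' Pairwise participant distances under three metrics
#'
#' `euclidean` is the ordinary Euclidean distance between feature rows;
#' `spearman` is `1 - rho` (Spearman rank correlation of the two rows);
#' `correlation` is `1 - r` (Pearson). Correlation metrics are undefined for
#' constant rows.
#'
#' @param matrix Participants-by-features numeric matrix (>= 2 rows; the
#'   correlation metrics additionally need >= 2 columns).
#' @param metric One of `"euclidean"`, `"spearman"`, `"correlation"`.
#' @return A `dist` object over participants.
#' @export
pairwise_distance <- function(matrix, metric = c("euclidean", "spearman", "correlation")) {
  metric <- match.arg(metric)
  if (is.null(dim(matrix)) || nrow(matrix) < 2L)
    stop("pairwise_distance: need at least 2 participants", call. = FALSE)
  if (metric == "euclidean")
    return(stats::dist(matrix, method = "euclidean"))
  if (ncol(matrix) < 2L)
    stop(sprintf("pairwise_distance('%s'): need at least 2 features", metric),
         call. = FALSE)
  sds <- apply(matrix, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("pairwise_distance('%s'): correlation undefined for constant row(s): %s",
                 metric, paste(rownames(matrix)[sds == 0], collapse = ", ")),
         call. = FALSE)
  method <- if (metric == "spearman") "spearman" else "pearson"
  r <- stats::cor(t(matrix), method = method)
  stats::as.dist(1 - r)
}

cluster_result <- function(labels, method, polarity_rule = "fixed",
                           inertia = NA_real_, linkage_height = NULL) {
  structure(list(labels = labels, method = method,
                 polarity_rule = polarity_rule, inertia = inertia,
                 linkage_height = linkage_height),
            class = "cluster_result")
}

# relabel so that the cluster containing the first participant is class 0
fix_first_zero <- function(assign, ids) {
  lab <- as.integer(assign != assign[1L])
  label_table(ids, lab, "cluster")
}

#' Two-class agglomerative hierarchical clustering
#'
#' Merges singleton clusters bottom-up under the chosen linkage and cuts the
#' tree at two clusters. Deterministic for a given row order.
#'
#' @param matrix Participants-by-features numeric matrix.
#' @param metric Distance metric, see [pairwise_distance()].
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @return A `cluster_result`; labels are 0/1 with the first participant's
#'   cluster labelled 0 (`polarity_rule = "fixed"`).
#' @export
hierarchical_two_clusters <- function(matrix,
                                      metric = c("euclidean", "spearman", "correlation"),
                                      linkage = c("average", "single", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  d <- pairwise_distance(matrix, metric)
  tree <- stats::hclust(d, method = linkage)
  assign <- stats::cutree(tree, k = 2L)
  cluster_result(fix_first_zero(assign, rownames(matrix)),
                 method = paste0("tree_", metric),
                 linkage_height = tree$height)
}

# k-means++ initial centers (Arthur & Vassilvitskii): first uniform, each
# further center drawn with probability proportional to squared distance to
# the nearest chosen center.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  centers[1L, ] <- m[sample.int(n, 1L), ]
  d2 <- rowSums((m - matrix(centers[1L, ], n, ncol(m), byrow = TRUE))^2)
  for (j in 2L:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- m[sample.int(n, 1L, prob = probs), ]
    dj <- rowSums((m - matrix(centers[j, ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

#' Two-class k-means with k-means++ restarts
#'
#' Lloyd iterations from k-means++ starts; the partition of lowest inertia
#' (total within-cluster sum of squares) over `n_init` restarts wins.
#' Reproducible for a fixed seed.
#'
#' @param matrix Participants-by-features numeric matrix with >= 2 distinct
#'   rows.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return A `cluster_result` with `inertia` set; labels 0/1, first
#'   participant's cluster = 0.
#' @export
kmeans_two_clusters <- function(matrix, seed, n_init = 10L, max_iter = 300L) {
  if (is.null(dim(matrix)) || nrow(matrix) < 2L)
    stop("kmeans_two_clusters: need at least 2 participants", call. = FALSE)
  if (nrow(unique(matrix)) < 2L)
    stop("kmeans_two_clusters: fewer than 2 distinct feature rows", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(matrix, 2L)
    if (nrow(unique(centers)) < 2L) next
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(matrix, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd")),
      error = function(e) NULL)   # e.g. a start that empties a cluster
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best))
    stop("kmeans_two_clusters: no valid start found", call. = FALSE)
  cluster_result(fix_first_zero(best$cluster, rownames(matrix)),
                 method = "kmeans", inertia = best$tot.withinss)
}

#' Align cluster polarity with a reference labelling
#'
#' Cluster labels are arbitrary: `rule = "best_match"` applies whichever
#' label permutation maximizes agreement with the reference, while
#' `rule = "fixed"` keeps the labels exactly as produced (mirroring analyses
#' that report raw, possibly below-chance agreement).
#'
#' @param result A `cluster_result`.
#' @param reference A [label_table()] over the same participants.
#' @param rule `"best_match"` or `"fixed"`.
#' @return The `cluster_result`, possibly with flipped labels and
#'   `polarity_rule` updated.
#' @export
assign_polarity <- function(result, reference, rule = c("best_match", "fixed")) {
  rule <- match.arg(rule)
  ids <- names(result$labels)
  if (!setequal(ids, names(reference)))
    stop("assign_polarity: participant sets differ", call. = FALSE)
  if (rule == "fixed") {
    result$polarity_rule <- "fixed"
    return(result)
  }
  ref <- reference[ids]
  agree <- mean(as.integer(result$labels) == as.integer(ref))
  if (1 - agree > agree) {
    flipped <- label_table(ids, 1L - as.integer(result$labels), "cluster")
    result$labels <- flipped
  }
  result$polarity_rule <- "best_match"
  result
}
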