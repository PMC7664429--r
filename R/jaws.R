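#' Score one JAWS response set
#'
#' Two complementary scorings: the positive (`pos`) and negative (`neg`)
#' subscale sums over their six items each, and the `total`, which sums all
#' twelve items after reverse-coding the negatively keyed ones
#' (recoded item = 6 - raw). Higher total therefore always means more
#' positive affect, and the identity `total = pos + 36 - neg` holds.
#'
#' @param resp A [jaws_responses()] object.
#' @return List with `participant_id`, `total` (12..60), `pos` (6..30),
#'   `neg` (6..30).
#' @export
score_jaws <- function(resp) {
  stopifnot(inherits(resp, "jaws_responses"))
  pos_idx <- resp$polarity == "positive"
  pos <- sum(resp$items[pos_idx])
  neg <- sum(resp$items[!pos_idx])
  total <- pos + sum(6L - resp$items[!pos_idx])
  stopifnot(total == pos + 36L - neg)
  list(participant_id = resp$participant_id,
       total = total, pos = pos, neg = neg)
}

#' Score a list of JAWS responses into a table
#'
#' @param responses List of [jaws_responses()].
#' @return data.frame with columns `participant_id`, `total`, `pos`, `neg`.
#' @export
score_jaws_table <- function(responses) {
  rows <- lapply(responses, score_jaws)
  data.frame(participant_id = vapply(rows, `[[`, character(1), "participant_id"),
             total = vapply(rows, `[[`, numeric(1), "total"),
             pos = vapply(rows, `[[`, numeric(1), "pos"),
             neg = vapply(rows, `[[`, numeric(1), "neg"),
             stringsAsFactors = FALSE)
}

#' Two-class reference labels from one score scale
#'
#' Partitions the scores by exact one-dimensional two-means (the optimal
#' contiguous split of the sorted values, found by enumeration — no random
#' restarts are needed in one dimension, so the result is deterministic and
#' the `seed` argument is accepted only for interface symmetry with the
#' other clusterers). The induced threshold is the midpoint between the
#' maximum of the lower cluster and the minimum of the upper cluster; the
#' high-score cluster is labelled 1.
#'
#' @param scores Named numeric vector (names = participant ids), n >= 2,
#'   not all equal.
#' @param seed Unused; present for interface symmetry.
#' @return List: `labels` (a [label_table()], provenance `"jaws"`) and
#'   `threshold`.
#' @export
reference_labels <- function(scores, seed = NULL) {
  if (length(scores) < 2L)
    stop("reference_labels: need at least 2 scores", call. = FALSE)
  x <- as.numeric(scores)
  if (length(unique(x)) == 1L)
    stop("reference_labels: all scores equal — no two-class structure", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best_split <- NA_integer_
  best_w <- Inf
  for (s in 1:(n - 1L)) {           # lower cluster = xs[1..s]
    lo <- xs[1:s]; hi <- xs[(s + 1L):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best_w - 1e-12) {
      best_w <- w
      best_split <- s
    }
  }
  threshold <- (xs[best_split] + xs[best_split + 1L]) / 2
  lab <- as.integer(x > threshold)
  list(labels = label_table(names(scores), lab, "jaws"),
       threshold = threshold)
}

#' Dichotomize scores at a fixed threshold
#'
#' Label 1 is assigned iff `score > threshold` (strict). On the `neg` scale
#' label 1 therefore means "negative-dominant". The threshold must lie
#' within the scale's possible range (total 12..60, subscales 6..30).
#'
#' @param scores data.frame from [score_jaws_table()].
#' @param scale `"total"`, `"pos"`, or `"neg"`.
#' @param threshold Cut point.
#' @return A [label_table()] with provenance `"jaws"`.
#' @export
dichotomize <- function(scores, scale = c("total", "pos", "neg"), threshold) {
  scale <- match.arg(scale)
  rng <- if (scale == "total") c(12, 60) else c(6, 30)
  if (threshold < rng[1L] || threshold > rng[2L])
    stop(sprintf("dichotomize: threshold %g outside the %s range [%g, %g]",
                 threshold, scale, rng[1L], rng[2L]), call. = FALSE)
  label_table(scores$participant_id,
              as.integer(scores[[scale]] > threshold), "jaws")
}

#' Positivity (Losada) ratio
#'
#' Ratio of the mean positive-affect score to the mean negative-affect
#' score. Values around 3 are classically read as a flourishing balance;
#' lower values indicate that positive emotions do not dominate.
#'
#' @param mean_pos Mean positive subscale score.
#' @param mean_neg Mean negative subscale score (> 0).
#' @return `mean_pos / mean_neg`.
#' @export
positivity_ratio <- function(mean_pos, mean_neg) {
  if (mean_neg <= 0)
    stop("positivity_ratio: mean negative score must be > 0", call. = FALSE)
  mean_pos / mean_neg
}
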