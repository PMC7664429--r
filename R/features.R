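#' Canonical per-segment EDA feature names
#'
#' Sixteen statistical indices, five regression-line indices, and five
#' skin-conductance-response (GSR) event indices. `rms` (root mean square of
#' the signal) and `reg_rmse` (root mean square of the residuals about the
#' OLS trend) are kept as separate features.
#'
#' @return Character vector of 26 feature names.
#' @export
canonical_features <- function() {
  c("mean", "standard_deviation", "median", "variance", "p25", "p75",
    "quartile_deviation", "minimum", "maximum", "moment4", "moment5",
    "skewness", "kurtosis", "rms", "total_sum", "entropy",
    "reg_slope", "reg_intercept", "reg_mean_abs_residual", "reg_rmse",
    "n_crossings",
    "n_gsr", "rpm", "gsr_energy", "n_sig_gsr", "sig_gsr_energy")
}

# Interior strict local maxima of v, with plateaus credited to their first
# sample: position i qualifies if v[i] > v[i-1] and the first following value
# different from v[i] is smaller.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Detect GSR events on a phasic trace
#'
#' A galvanic skin response is triggered by a strict interior local maximum
#' of the first-difference (derivative) of the phasic component whose value
#' is positive — the point of steepest conductance rise. The event peak is
#' the first subsequent local maximum of the phasic trace itself (the last
#' sample if the trace never turns down), and the amplitude is the phasic
#' value there. Events whose amplitude exceeds `sig_threshold` (1.5 uS) are
#' flagged significant. Candidate events with non-positive peak amplitude
#' are discarded.
#'
#' @param phasic Numeric phasic conductance trace (uS), length >= 3.
#' @param fs Sampling rate in Hz (recorded on the events, not used for
#'   detection).
#' @param sig_threshold Significance threshold in uS (default 1.5).
#' @return data.frame with columns `trigger_index`, `peak_index`,
#'   `amplitude`, `energy`, `significant` (zero rows when no event).
#' @export
detect_gsr_events <- function(phasic, fs = 4, sig_threshold = 1.5) {
  phasic <- as.numeric(phasic)
  n <- length(phasic)
  if (n < 3L)
    stop("detect_gsr_events: phasic trace must have at least 3 samples", call. = FALSE)
  d <- diff(phasic)
  trig_d <- local_maxima(d)
  trig_d <- trig_d[d[trig_d] > 0]
  # derivative element i spans samples i -> i+1; the rise tops out at i+1
  triggers <- trig_d + 1L
  peaks_all <- local_maxima(phasic)
  ev <- lapply(triggers, function(tr) {
    p <- peaks_all[peaks_all >= tr]
    peak <- if (length(p)) p[1L] else n
    amp <- phasic[peak]
    if (amp <= 0) return(NULL)
    data.frame(trigger_index = tr, peak_index = peak, amplitude = amp,
               energy = amp^2, significant = amp > sig_threshold)
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (length(ev) == 0L)
    return(data.frame(trigger_index = integer(0), peak_index = integer(0),
                      amplitude = numeric(0), energy = numeric(0),
                      significant = logical(0)))
  do.call(rbind, ev)
}

#' Aggregate GSR event features for one segment
#'
#' @param events Event table from [detect_gsr_events()].
#' @param duration Segment duration in seconds (> 0).
#' @return Named list: `n_gsr`, `rpm` (events per minute), `gsr_energy`
#'   (sum of squared amplitudes, uS^2), `n_sig_gsr`, `sig_gsr_energy`.
#' @export
gsr_features <- function(events, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop("gsr_features: duration must be > 0", call. = FALSE)
  n <- nrow(events)
  sig <- events$significant
  list(n_gsr = n,
       rpm = n * 60 / duration,
       gsr_energy = sum(events$energy),
       n_sig_gsr = sum(sig),
       sig_gsr_energy = sum(events$energy[sig]))
}

#' Statistical feature battery for one segment
#'
#' Conventions: variance and standard deviation use the n-1 denominator;
#' percentiles use linear interpolation; `moment4`/`moment5` are central
#' moments with the n denominator; skewness and (non-excess) kurtosis are
#' built from population moments and defined as 0 for a constant segment;
#' entropy is the base-2 Shannon entropy of a 16-bin histogram spanning
#' `[min, max]`; the `reg_*` indices come from the OLS fit of the samples on
#' their index, and `n_crossings` counts sign changes of the OLS residuals
#' (zero residuals carry no sign).
#'
#' @param samples Numeric vector, length >= 4.
#' @param entropy_bins Number of histogram bins for the entropy estimate.
#' @return Named list over the 21 non-GSR canonical features.
#' @export
statistical_features <- function(samples, entropy_bins = 16L) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 4L)
    stop("statistical_features: need at least 4 samples", call. = FALSE)
  m <- mean(x)
  cen <- x - m
  m2 <- mean(cen^2)
  m3 <- mean(cen^3)
  m4 <- mean(cen^4)
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  ent <- shannon_entropy(x, entropy_bins)
  i <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, i), x)
  res <- fit$residuals
  list(mean = m,
       standard_deviation = stats::sd(x),
       median = q[2L],
       variance = stats::var(x),
       p25 = q[1L],
       p75 = q[3L],
       quartile_deviation = (q[3L] - q[1L]) / 2,
       minimum = min(x),
       maximum = max(x),
       moment4 = m4,
       moment5 = mean(cen^5),
       skewness = skew,
       kurtosis = kurt,
       rms = sqrt(mean(x^2)),
       total_sum = sum(x),
       entropy = ent,
       reg_slope = unname(fit$coefficients[2L]),
       reg_intercept = unname(fit$coefficients[1L]),
       reg_mean_abs_residual = mean(abs(res)),
       reg_rmse = sqrt(mean(res^2)),
       # residuals within rounding error of the line carry no sign
       n_crossings = sign_changes(res, tol = 1e-10 * max(abs(x), 1)))
}

shannon_entropy <- function(x, bins = 16L) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

sign_changes <- function(res, tol = 0) {
  s <- sign(res)
  s <- s[abs(res) > tol & s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Full feature vector for one segment
#'
#' Statistics are computed on the (by default raw) segment samples; GSR
#' features on events detected from the phasic component of the denoised
#' segment.
#'
#' @param segment A `segment`.
#' @param tonic_phasic Output of [decompose_tonic_phasic()] for the (usually
#'   denoised) segment.
#' @param events Event table from [detect_gsr_events()]; detected on the
#'   phasic trace when omitted.
#' @param stats_on `"raw"` (default) to compute statistics on the segment's
#'   own samples, `"denoised"` to pass a pre-denoised segment through.
#' @return Named numeric vector over [canonical_features()].
#' @export
segment_features <- function(segment, tonic_phasic, events = NULL,
                             stats_on = c("raw", "denoised")) {
  stats_on <- match.arg(stats_on)
  if (is.null(events))
    events <- detect_gsr_events(tonic_phasic$phasic, segment$fs)
  st <- statistical_features(segment$samples)
  gf <- gsr_features(events, segment$duration)
  out <- unlist(c(st, gf))
  out[canonical_features()]
}

#' Assemble a participants-by-features matrix for one exercise
#'
#' @param cohort List of entries, each a list with elements `segment`,
#'   `tonic_phasic` and optionally `events`, all from the same exercise.
#' @return Numeric matrix, one row per participant (rownames = ids), one
#'   column per canonical feature; attribute `exercise_id`.
#' @export
extract_feature_matrix <- function(cohort) {
  if (length(cohort) == 0L)
    stop("extract_feature_matrix: empty cohort", call. = FALSE)
  ex <- vapply(cohort, function(e) e$segment$exercise_id, numeric(1))
  if (length(unique(ex)) != 1L)
    stop("extract_feature_matrix: entries span multiple exercises", call. = FALSE)
  ids <- vapply(cohort, function(e) e$segment$participant_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("extract_feature_matrix: duplicate participant '%s'",
                 ids[anyDuplicated(ids)]), call. = FALSE)
  rows <- lapply(cohort, function(e)
    segment_features(e$segment, e$tonic_phasic, e$events))
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  structure(m, exercise_id = ex[1L])
}
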