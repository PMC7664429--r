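#' Cut a session into exercise segments at its begin/end markers
#'
#' Markers are interpreted as consecutive begin/end pairs in protocol order
#' (Exercise 1, 2, 3, ...). Each segment takes the half-open sample window
#' `[begin, end)`: sample `i` belongs to the segment when
#' `begin <= start_time + (i - 1)/fs < end`.
#'
#' @param session An [eda_session()] whose markers pair up.
#' @return List of `segment` objects (fields `participant_id`, `exercise_id`,
#'   `fs`, `samples`, `duration`).
#' @export
segment_by_markers <- function(session) {
  validate_eda_session(session)
  m <- session$markers
  if (length(m) == 0L || length(m) %% 2L != 0L)
    stop(sprintf("segment_by_markers [%s]: markers must form begin/end pairs (got %d)",
                 session$participant_id, length(m)), call. = FALSE)
  n_pairs <- length(m) / 2L
  t0 <- session$start_time
  fs <- session$fs
  times <- t0 + (seq_along(session$samples) - 1) / fs
  lapply(seq_len(n_pairs), function(k) {
    begin <- m[2L * k - 1L]
    end <- m[2L * k]
    if (end <= begin)
      stop(sprintf("segment_by_markers [%s]: pair %d has end <= begin",
                   session$participant_id, k), call. = FALSE)
    idx <- which(times >= begin & times < end)
    if (length(idx) == 0L)
      stop(sprintf("segment_by_markers [%s]: pair %d selects no samples",
                   session$participant_id, k), call. = FALSE)
    structure(list(participant_id = session$participant_id,
                   exercise_id = k,
                   fs = fs,
                   samples = session$samples[idx],
                   duration = length(idx) / fs),
              class = "segment")
  })
}

#' Maximum wavelet decomposition level for a segment
#'
#' `floor(log2(n))`, capped at 10. A segment of fewer than 2 samples cannot
#' be decomposed.
#'
#' @param n Segment length in samples (scalar or vector).
#' @return Integer level(s).
#' @export
max_decomposition_level <- function(n) {
  n <- as.numeric(n)
  if (any(!is.finite(n)) || any(n < 2))
    stop("max_decomposition_level: n must be >= 2", call. = FALSE)
  lvl <- floor(log2(n))
  # guard against floating-point log2 at exact powers of two
  lvl <- ifelse(2^lvl > n, lvl - 1, lvl)
  lvl <- ifelse(2^(lvl + 1) <= n, lvl + 1, lvl)
  as.integer(pmin(lvl, 10))
}

# sym4 (least-asymmetric Daubechies, 4 vanishing moments) analysis filters.
sym4_filters <- function() {
  dec_lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
              0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783, 0.03222310060404270)
  dec_hi <- rev(dec_lo) * (-1)^(seq_along(dec_lo) - 1)
  list(g = dec_lo, h = dec_hi)
}

# Maximal-overlap DWT (circular boundary) of x to `level` levels.
# Returns list(W = list of wavelet coefficient vectors, V = final scaling
# coefficients). Filters are rescaled by 1/sqrt(2) per the MODWT definition,
# which makes the transform exact for any sample count.
modwt <- function(x, level, filters = sym4_filters()) {
  n <- length(x)
  h <- filters$h / sqrt(2)
  g <- filters$g / sqrt(2)
  L <- length(h)
  W <- vector("list", level)
  V <- x
  t0 <- seq_len(n) - 1
  for (j in seq_len(level)) {
    step <- 2^(j - 1)
    Wj <- numeric(n)
    Vj <- numeric(n)
    for (l in seq_len(L)) {
      idx <- (t0 - step * (l - 1)) %% n + 1
      Wj <- Wj + h[l] * V[idx]
      Vj <- Vj + g[l] * V[idx]
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

# Inverse MODWT; exact reconstruction for any n.
imodwt <- function(coeffs, filters = sym4_filters()) {
  h <- filters$h / sqrt(2)
  g <- filters$g / sqrt(2)
  L <- length(h)
  V <- coeffs$V
  n <- length(V)
  t0 <- seq_len(n) - 1
  for (j in rev(seq_along(coeffs$W))) {
    step <- 2^(j - 1)
    Wj <- coeffs$W[[j]]
    V0 <- numeric(n)
    for (l in seq_len(L)) {
      idx <- (t0 + step * (l - 1)) %% n + 1
      V0 <- V0 + h[l] * Wj[idx] + g[l] * V[idx]
    }
    V <- V0
  }
  V
}

#' Wavelet-denoise a segment
#'
#' Maximal-overlap discrete wavelet transform with a Symlet-4 filter bank,
#' soft thresholding with a per-level universal threshold
#' `sigma_j * sqrt(2 log n)` (`sigma_j` = MAD estimate from the level-j
#' coefficients), then inverse transform. A constant segment passes through
#' unchanged.
#'
#' @param segment A `segment` (from [segment_by_markers()]) or numeric vector.
#' @param wavelet Wavelet name; only the Symlet-4 filter bank (`"sym4"`) is
#'   built in.
#' @param level Decomposition level; defaults to the capped maximum for the
#'   segment length. Must not exceed [max_decomposition_level()].
#' @return Object of the same shape as the input, with denoised samples.
#' @export
wavelet_denoise <- function(segment, wavelet = "sym4", level = NULL) {
  x <- if (inherits(segment, "segment")) segment$samples else as.numeric(segment)
  if (!identical(wavelet, "sym4"))
    stop(sprintf("wavelet_denoise: unknown wavelet '%s' (built-in: sym4)", wavelet),
         call. = FALSE)
  n <- length(x)
  filters <- sym4_filters()
  if (n < length(filters$g))
    stop(sprintf("wavelet_denoise: segment of %d samples is shorter than the filter support (%d)",
                 n, length(filters$g)), call. = FALSE)
  cap <- max_decomposition_level(n)
  if (is.null(level)) level <- cap
  if (level > cap)
    stop(sprintf("wavelet_denoise: level %d exceeds the maximum %d for %d samples",
                 level, cap, n), call. = FALSE)
  if (level < 1L)
    stop("wavelet_denoise: level must be >= 1", call. = FALSE)
  dec <- modwt(x, level, filters)
  # noise SD estimated once from the finest detail level (MAD); under the
  # MODWT white noise decays as sigma / 2^(j/2) across levels, giving a
  # level-dependent universal threshold
  sigma <- sqrt(2) * stats::median(abs(dec$W[[1L]])) / 0.6745
  for (j in seq_len(level)) {
    thr <- sigma / 2^(j / 2) * sqrt(2 * log(n))
    w <- dec$W[[j]]
    dec$W[[j]] <- sign(w) * pmax(abs(w) - thr, 0)
  }
  y <- imodwt(dec, filters)
  if (inherits(segment, "segment")) {
    segment$samples <- y
    segment
  } else {
    y
  }
}

#' Split a segment into tonic and phasic components
#'
#' The tonic component is the slow baseline: either the per-segment ordinary
#' least squares trend (`method = "linear"`, the default — the slope of that
#' line is itself one of the tonicity features) or a centered moving median
#' (`method = "moving_median"`). The phasic component is the residual, so
#' `tonic + phasic` reconstructs the input exactly.
#'
#' @param segment A `segment` or numeric vector.
#' @param method `"linear"` or `"moving_median"`.
#' @param window Moving-median window in seconds (default 4).
#' @param fs Sampling rate, required when `segment` is a bare vector and
#'   `method = "moving_median"`.
#' @return List with fields `tonic`, `phasic`, `method`.
#' @export
decompose_tonic_phasic <- function(segment, method = c("linear", "moving_median"),
                                   window = 4, fs = NULL) {
  method <- match.arg(method)
  x <- if (inherits(segment, "segment")) segment$samples else as.numeric(segment)
  if (inherits(segment, "segment")) fs <- segment$fs
  n <- length(x)
  if (method == "linear") {
    i <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, i), x)
    tonic <- fit$fitted.values
  } else {
    if (is.null(fs))
      stop("decompose_tonic_phasic: fs is required for moving_median on a bare vector",
           call. = FALSE)
    w <- max(2L, round(window * fs))
    if (w > n)
      stop(sprintf("decompose_tonic_phasic: window of %d samples exceeds segment length %d",
                   w, n), call. = FALSE)
    if (w %% 2L == 0L) w <- w + 1L   # runmed needs an odd window
    w <- min(w, if (n %% 2L == 1L) n else n - 1L)
    tonic <- as.numeric(stats::runmed(x, k = w, endrule = "median"))
  }
  structure(list(tonic = as.numeric(tonic),
                 phasic = x - as.numeric(tonic),
                 method = method),
            class = "tonic_phasic")
}
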