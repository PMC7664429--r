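# Independent brute-force oracles. These deliberately use different
# algorithms from the package code paths they check.

# Minimal 2-cluster WCSS by exhaustive enumeration of every assignment of
# the values into two non-empty groups.
bf_wcss2 <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- x[g]; b <- x[!g]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) best <- w
  }
  best
}

# Total within-cluster sum of squares of the best 2-partition of the rows
# of m, by exhaustive enumeration.
bf_best_partition_inertia <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- m[g, , drop = FALSE]; b <- m[!g, , drop = FALSE]
    w <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (w < best) best <- w
  }
  best
}

# Run-length-encoding scan for interior strict (plateau-first) local maxima
# of v: a run is a maximum when its neighbours on both sides are lower; the
# candidate index is the first sample of the run and must not touch either
# boundary.
bf_local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next
    if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L])
      out <- c(out, starts[k])
  }
  out[out >= 2L]
}

# Brute-force GSR detector mirroring the event definition: positive interior
# local maxima of the first difference trigger events; the peak is the first
# following phasic local maximum (or the last sample); events with
# non-positive peak amplitude are dropped.
bf_gsr <- function(phasic, thr = 1.5) {
  d <- diff(phasic)
  trig <- bf_local_maxima(d)
  trig <- trig[d[trig] > 0] + 1L
  peaks <- bf_local_maxima(phasic)
  rows <- list()
  for (tr in trig) {
    after <- peaks[peaks >= tr]
    pk <- if (length(after)) after[1L] else length(phasic)
    amp <- phasic[pk]
    if (amp > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(trigger_index = tr, peak_index = pk, amplitude = amp,
                   energy = amp^2, significant = amp > thr)
  }
  if (!length(rows))
    return(data.frame(trigger_index = integer(0), peak_index = integer(0),
                      amplitude = numeric(0), energy = numeric(0),
                      significant = logical(0)))
  do.call(rbind, rows)
}

# Small cohort configuration used where full study-scale runs would be
# needlessly slow.
tiny_synth <- function(seed = 1L, ...) {
  synth_config(n_participants = 8L, seed = seed, ...)
}

# Deterministic two-cloud feature matrix for clustering tests.
two_clouds <- function(n_per = 5L, sep = 10, seed = 42L) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * 3, 0, 0.3), n_per),
             matrix(rnorm(n_per * 3, sep, 0.3), n_per))
  rownames(m) <- sprintf("P%02d", seq_len(2 * n_per))
  m
}
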