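#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the study conditions the pipeline is designed
#' for: a 41-participant cohort recorded at 4 Hz over three exercises of
#' 60, 10 and 10 s (begin/end markers around each, separated by short
#' rests), with a latent two-class emotion structure. Class membership
#' drives both the skin-conductance-response process (event rate and
#' amplitude) and the questionnaire responses (latent affect trait). The
#' `separation` knob scales the class contrast: at 1 the high-arousal class
#' fires ~8 events/min with ~2 uS amplitudes against ~1 event/min at
#' ~0.5 uS, and at 0 the two classes are identical (pure null).
#'
#' @param n_participants Cohort size (default 41).
#' @param fs Sampling rate in Hz (default 4).
#' @param durations Exercise durations in seconds (default `c(60, 10, 10)`).
#' @param class_proportions Proportions of the low/high class, summing to 1.
#' @param separation Class-contrast multiplier (default 1).
#' @param scr_rate Events per minute for the low and high class at
#'   `separation = 1`.
#' @param scr_amp Median SCR amplitudes (uS, lognormal) at `separation = 1`.
#' @param amp_sdlog Lognormal sdlog of event amplitudes.
#' @param baseline_range Tonic baseline draw range in uS.
#' @param drift_range Tonic drift slope range in uS/s.
#' @param noise_sd Gaussian measurement noise SD in uS.
#' @param kernel_rise,kernel_decay Bateman SCR kernel time constants in s.
#' @param rest Seconds of rest before, between and after exercises.
#' @param trait_sep Latent JAWS trait class means are `+/- separation *
#'   trait_sep / 2` (trait SD 1).
#' @param item_correlation Correlation of each Likert item with the latent
#'   trait.
#' @param seed RNG seed.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 41L, fs = 4, durations = c(60, 10, 10),
                         class_proportions = c(0.5, 0.5), separation = 1,
                         scr_rate = c(1, 8), scr_amp = c(0.5, 2),
                         amp_sdlog = 0.3, baseline_range = c(2, 6),
                         drift_range = c(0, 0.01), noise_sd = 0.05,
                         kernel_rise = 0.75, kernel_decay = 4, rest = 5,
                         trait_sep = 2.5, item_correlation = 0.9, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants), fs = fs,
              durations = durations, class_proportions = class_proportions,
              separation = separation, scr_rate = scr_rate, scr_amp = scr_amp,
              amp_sdlog = amp_sdlog, baseline_range = baseline_range,
              drift_range = drift_range, noise_sd = noise_sd,
              kernel_rise = kernel_rise, kernel_decay = kernel_decay,
              rest = rest, trait_sep = trait_sep,
              item_correlation = item_correlation, seed = as.integer(seed))
  stopifnot(cfg$n_participants >= 2L, cfg$fs > 0, all(cfg$durations > 0),
            abs(sum(cfg$class_proportions) - 1) < 1e-9,
            all(cfg$scr_rate > 0), all(cfg$scr_amp > 0), cfg$noise_sd >= 0,
            cfg$kernel_rise > 0, cfg$kernel_decay > cfg$kernel_rise,
            cfg$separation >= 0)
  class(cfg) <- "synth_config"
  cfg
}

# per-class event rate (events/min) and amplitude meanlog after applying the
# separation multiplier; class_id is 0 (low) or 1 (high)
class_params <- function(class_id, cfg) {
  s <- cfg$separation
  rate_mid <- mean(cfg$scr_rate)
  rate_half <- diff(cfg$scr_rate) / 2
  lamp <- log(cfg$scr_amp)
  amp_mid <- mean(lamp)
  amp_half <- diff(lamp) / 2
  sgn <- if (class_id == 1L) 1 else -1
  list(rate = max(rate_mid + sgn * s * rate_half, 0),
       amp_meanlog = amp_mid + sgn * s * amp_half)
}

# Bateman-type SCR kernel normalized to unit peak
scr_kernel <- function(t, rise, decay) {
  t_peak <- (decay * rise / (decay - rise)) * log(decay / rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / peak)
}

#' Simulate one participant's EDA session
#'
#' Tonic baseline plus linear drift, Poisson-timed SCR events convolved
#' with a biexponential (Bateman) kernel, and Gaussian noise; conductance
#' clipped positive. Markers delimit the three exercises in begin/end
#' pairs. Uses the current RNG state.
#'
#' @param participant_id Participant id.
#' @param class_id Latent class, 0 (low arousal) or 1 (high arousal).
#' @param cfg A [synth_config()].
#' @param start_time Recording start (seconds since epoch).
#' @return An [eda_session()].
#' @export
simulate_session <- function(participant_id, class_id, cfg,
                             start_time = 1.6e9) {
  p <- class_params(class_id, cfg)
  fs <- cfg$fs
  rest <- cfg$rest
  total <- rest + sum(cfg$durations + rest)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  baseline <- stats::runif(1, cfg$baseline_range[1L], cfg$baseline_range[2L])
  drift <- stats::runif(1, cfg$drift_range[1L], cfg$drift_range[2L])
  x <- baseline + drift * t
  n_events <- stats::rpois(1, p$rate * total / 60)
  if (n_events > 0) {
    times <- sort(stats::runif(n_events, 0, total))
    amps <- stats::rlnorm(n_events, p$amp_meanlog, cfg$amp_sdlog)
    for (i in seq_len(n_events))
      x <- x + amps[i] * scr_kernel(t - times[i], cfg$kernel_rise, cfg$kernel_decay)
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  x <- pmax(x, 1e-3)
  begins <- rest + cumsum(c(0, utils::head(cfg$durations, -1) + rest))
  markers <- start_time + as.vector(rbind(begins, begins + cfg$durations))
  eda_session(participant_id, start_time, fs, x, markers)
}

#' Simulate one participant's JAWS responses
#'
#' A single latent affect trait per participant (class mean plus unit
#' Gaussian noise) drives all twelve items: each item mixes the trait
#' (negatively keyed items load on its negation) with independent noise at
#' the configured item-trait correlation and is discretized through
#' equal-width thresholds into the 1..5 Likert range.
#'
#' @param participant_id Participant id.
#' @param class_id Latent class (1 = positive-affect class).
#' @param cfg A [synth_config()].
#' @param positive_items Indices of positively keyed items.
#' @return A [jaws_responses()].
#' @export
simulate_jaws <- function(participant_id, class_id, cfg, positive_items = 1:6) {
  mu <- (if (class_id == 1L) 1 else -1) * cfg$separation * cfg$trait_sep / 2
  z <- stats::rnorm(1, mu, 1)
  rho <- cfg$item_correlation
  items <- vapply(1:12, function(i) {
    signed <- if (i %in% positive_items) z else -z
    latent <- rho * signed + sqrt(1 - rho^2) * stats::rnorm(1)
    min(max(findInterval(latent, c(-1.5, -0.5, 0.5, 1.5)) + 1L, 1L), 5L)
  }, integer(1))
  jaws_responses(participant_id, items, positive_items)
}

#' Simulate a full paired cohort
#'
#' Reproducible from `cfg$seed`: sessions with begin/end markers per
#' exercise, JAWS responses, and the ground-truth class labels.
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_cohort`: `sessions`, `responses`, `truth`
#'   (a [label_table()], provenance `"truth"`), `config`.
#' @export
simulate_cohort <- function(cfg = synth_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  n1 <- round(n * cfg$class_proportions[2L])
  classes <- sample(c(rep(0L, n - n1), rep(1L, n1)))
  sessions <- vector("list", n)
  responses <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- simulate_session(ids[i], classes[i], cfg)
    responses[[i]] <- simulate_jaws(ids[i], classes[i], cfg)
  }
  structure(list(sessions = sessions, responses = responses,
                 truth = label_table(ids, classes, "truth"),
                 config = cfg),
            class = "synth_cohort")
}

#' Write a synthetic cohort as an E4-style directory tree
#'
#' Layout: `P###/EDA.csv` and `P###/tags.csv` per participant, plus
#' `jaws.csv`, `truth.csv` and `synth_meta.json` (all generator parameters)
#' at the top level.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    pdir <- file.path(dir, s$participant_id)
    dir.create(pdir, showWarnings = FALSE)
    write_eda_csv(s, file.path(pdir, "EDA.csv"))
    writeLines(format(s$markers, digits = 17, trim = TRUE),
               file.path(pdir, "tags.csv"))
  }
  items <- t(vapply(cohort$responses, function(r) r$items, integer(12)))
  df <- data.frame(participant_id = vapply(cohort$responses, `[[`,
                                           character(1), "participant_id"),
                   items)
  names(df) <- c("participant_id", paste0("item", 1:12))
  utils::write.csv(df, file.path(dir, "jaws.csv"), row.names = FALSE, quote = FALSE)
  write_labels_csv(cohort$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "synth_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param positive_items Indices of positively keyed JAWS items.
#' @return List with `sessions`, `responses`, and `truth` (when
#'   `truth.csv` is present).
#' @export
read_cohort <- function(dir, positive_items = 1:6) {
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  sessions <- lapply(pdirs, function(pd) {
    tags <- read_tags_csv(file.path(pd, "tags.csv"))
    read_eda_csv(file.path(pd, "EDA.csv"), participant_id = basename(pd),
                 markers = tags)
  })
  responses <- read_jaws_csv(file.path(dir, "jaws.csv"), positive_items)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read_labels_csv(truth_path, "truth") else NULL
  list(sessions = sessions, responses = responses, truth = truth)
}
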