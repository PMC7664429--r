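#' Construct an EDA session object
#'
#' An `eda_session` bundles one participant's skin-conductance trace with its
#' acquisition metadata: the recording start time, the sampling rate, and the
#' event markers delimiting the exercise windows. Sample `i` (1-based) is
#' taken to occur at `start_time + (i - 1) / fs` seconds (sample-start
#' convention).
#'
#' @param participant_id Participant identifier (single string).
#' @param start_time Recording start, in seconds since the epoch.
#' @param fs Sampling rate in Hz (the E4 wristband exports EDA at 4 Hz).
#' @param samples Numeric vector of conductance values in microsiemens.
#' @param markers Numeric vector of event-marker timestamps (seconds since
#'   epoch), non-decreasing, each within the recording.
#' @return An object of class `eda_session`.
#' @export
eda_session <- function(participant_id, start_time, fs, samples,
                        markers = numeric(0)) {
  s <- structure(
    list(participant_id = as.character(participant_id),
         start_time = as.numeric(start_time),
         fs = as.numeric(fs),
         samples = as.numeric(samples),
         markers = as.numeric(markers)),
    class = "eda_session")
  validate_eda_session(s)
  s
}

validate_eda_session <- function(s) {
  if (length(s$fs) != 1L || !is.finite(s$fs) || s$fs <= 0)
    stop("eda_session: sampling rate fs must be a single value > 0", call. = FALSE)
  if (length(s$samples) == 0L)
    stop("eda_session: samples must be non-empty", call. = FALSE)
  if (!all(is.finite(s$samples)))
    stop("eda_session: all samples must be finite", call. = FALSE)
  if (is.unsorted(s$markers))
    stop("eda_session: markers must be non-decreasing", call. = FALSE)
  t_end <- s$start_time + length(s$samples) / s$fs
  if (length(s$markers) &&
      (min(s$markers) < s$start_time || max(s$markers) > t_end))
    stop("eda_session: markers must lie within the recording", call. = FALSE)
  invisible(s)
}

#' @export
print.eda_session <- function(x, ...) {
  cat(sprintf("<eda_session> %s: %d samples @ %g Hz (%.1f s), %d markers\n",
              x$participant_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, length(x$markers)))
  invisible(x)
}

#' Read an Empatica-E4-dialect EDA CSV file
#'
#' The E4 export dialect: line 1 is the recording start timestamp (seconds
#' since epoch), line 2 the sampling rate in Hz, and every following line one
#' conductance value in microsiemens.
#'
#' @param path Path to the EDA CSV file.
#' @param participant_id Participant id to attach; defaults to the name of
#'   the directory containing the file.
#' @param markers Optional marker timestamps (e.g. from [read_tags_csv()]).
#' @return An [eda_session()].
#' @export
read_eda_csv <- function(path, participant_id = basename(dirname(normalizePath(path))),
                         markers = numeric(0)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop(sprintf("'%s': expected a 2-line header (start timestamp, sample rate)", path),
         call. = FALSE)
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_time))
    stop(sprintf("'%s': line 1 ('%s') is not a numeric start timestamp", path, lines[1L]),
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(fs))
    stop(sprintf("'%s': line 2 ('%s') is not a numeric sample rate", path, lines[2L]),
         call. = FALSE)
  if (fs <= 0)
    stop(sprintf("'%s': sample rate must be > 0, got %g (line 2)", path, fs),
         call. = FALSE)
  data <- lines[-(1:2)]
  if (length(data) == 0L)
    stop(sprintf("'%s': no data lines after the header", path), call. = FALSE)
  samples <- suppressWarnings(as.numeric(data))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    stop(sprintf("'%s': non-numeric sample '%s' at line %d", path, data[bad], bad + 2L),
         call. = FALSE)
  }
  eda_session(participant_id, start_time, fs, samples, markers)
}

#' Write an EDA session in the E4 CSV dialect
#'
#' Values are serialized at full precision so that a write/read round trip
#' reproduces the samples exactly.
#'
#' @param session An [eda_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eda_csv <- function(session, path) {
  validate_eda_session(session)
  writeLines(c(format(session$start_time, digits = 17, scientific = FALSE),
               format(session$fs, digits = 17),
               format(session$samples, digits = 17, trim = TRUE)),
             path)
  invisible(path)
}

#' Read an event-marker (tags) CSV file
#'
#' One timestamp (seconds since epoch) per line. Markers delimit exercises in
#' begin/end pairs and must be non-decreasing.
#'
#' @param path Path to the tags CSV.
#' @return Numeric vector of marker timestamps (possibly empty, with a
#'   warning).
#' @export
read_tags_csv <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning(sprintf("'%s': no markers found", path), call. = FALSE)
    return(numeric(0))
  }
  tags <- suppressWarnings(as.numeric(lines))
  if (anyNA(tags)) {
    bad <- which(is.na(tags))[1L]
    stop(sprintf("'%s': non-numeric marker '%s' at line %d", path, lines[bad], bad),
         call. = FALSE)
  }
  if (is.unsorted(tags))
    stop(sprintf("'%s': marker timestamps must be non-decreasing", path), call. = FALSE)
  tags
}

#' Construct JAWS questionnaire responses
#'
#' The short-form JAWS has 12 Likert items scored 1 (never) to 5 (very
#' often); six items describe positive and six negative emotions.
#'
#' @param participant_id Participant identifier.
#' @param items Integer vector of 12 responses, each in 1..5.
#' @param positive_items Indices (within 1..12) of the six positively keyed
#'   items; the remaining six are negatively keyed.
#' @return An object of class `jaws_responses`.
#' @export
jaws_responses <- function(participant_id, items, positive_items = 1:6) {
  items <- as.integer(items)
  if (length(items) != 12L)
    stop(sprintf("jaws_responses [%s]: expected 12 items, got %d",
                 participant_id, length(items)), call. = FALSE)
  if (anyNA(items) || any(items < 1L | items > 5L))
    stop(sprintf("jaws_responses [%s]: items must be integers in 1..5",
                 participant_id), call. = FALSE)
  positive_items <- sort(unique(as.integer(positive_items)))
  if (length(positive_items) != 6L || any(positive_items < 1L | positive_items > 12L))
    stop("jaws_responses: positive_items must be 6 distinct indices in 1..12",
         call. = FALSE)
  polarity <- rep("negative", 12L)
  polarity[positive_items] <- "positive"
  structure(list(participant_id = as.character(participant_id),
                 items = items, polarity = polarity),
            class = "jaws_responses")
}

#' Read a JAWS response table
#'
#' Expected layout: header `participant_id,item1,...,item12`, one row per
#' participant.
#'
#' @param path Path to the CSV file.
#' @param positive_items Indices of the positively keyed items (default 1:6).
#' @return List of [jaws_responses()] objects.
#' @export
read_jaws_csv <- function(path, positive_items = 1:6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != 13L)
    stop(sprintf("'%s': expected 13 columns (participant_id + 12 items), got %d",
                 path, ncol(df)), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    jaws_responses(df[[1L]][i], as.numeric(df[i, -1L]), positive_items)
  })
}

#' Construct a binary label table
#'
#' A named integer vector mapping participant ids to class labels in {0, 1},
#' tagged with its provenance (`"cluster"`, `"jaws"`, `"expert"`, or
#' `"truth"`).
#'
#' @param participant_id Character vector of unique participant ids.
#' @param label Integer vector of 0/1 labels, same length.
#' @param provenance Where the labels come from.
#' @return Named integer vector of class `label_table`.
#' @export
label_table <- function(participant_id, label,
                        provenance = c("cluster", "jaws", "expert", "truth")) {
  provenance <- match.arg(provenance)
  participant_id <- as.character(participant_id)
  label <- as.integer(label)
  if (length(participant_id) != length(label))
    stop("label_table: ids and labels differ in length", call. = FALSE)
  if (anyDuplicated(participant_id))
    stop("label_table: participant ids must be unique", call. = FALSE)
  if (anyNA(label) || !all(label %in% c(0L, 1L)))
    stop("label_table: labels must be 0 or 1", call. = FALSE)
  structure(stats::setNames(label, participant_id),
            provenance = provenance, class = "label_table")
}

#' Read expert (or any reference) labels from CSV
#'
#' Layout: header `participant_id,label`, labels in {0, 1}.
#'
#' @param path Path to the CSV file.
#' @param provenance Provenance tag, default `"expert"`.
#' @return A [label_table()].
#' @export
read_labels_csv <- function(path, provenance = "expert") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("'%s': expected columns participant_id,label", path), call. = FALSE)
  label_table(df[[1L]], df[[2L]], provenance)
}

#' Write a label table to CSV
#' @param labels A [label_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(participant_id = names(labels),
                              label = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' Header `participant_id,<feature names...>`; one file per exercise is the
#' intended use.
#'
#' @param matrix Numeric matrix with participant-id rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(participant_id = rownames(matrix), matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Path to the CSV file.
#' @return Numeric matrix with participant-id rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
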