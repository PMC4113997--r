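# Plain-text readers and writers: TSV tables with headers, one-float-per-
# line spike times, and an antidromic trial matrix with a sample-rate
# header line.  Every writer's output is parseable by its reader with
# lossless field values (times written at ns precision).

fmt_num <- function(x) sprintf("%.12g", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "songeval_io_error")
  utils::read.delim(path, sep = "\t", header = TRUE, fileEncoding = "UTF-8")
}

#' Write / read a feature track as TSV
#'
#' Columns: `time_ms`, `amplitude`, `fm`, `wiener_entropy`,
#' `pitch_goodness`, `pitch`, `silent`.
#'
#' @param track a `feature_track`.
#' @param path file path.
#' @return `path` (writer) / a data.frame (reader).
#' @export
write_feature_table <- function(track, path) {
  write_tsv(as.data.frame(track), path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) read_tsv(path)

#' Write / read syllable segments as TSV
#'
#' Columns `onset_ms`, `offset_ms` (half-open intervals).
#'
#' @param segments data.frame with `onset_ms`, `offset_ms`.
#' @param path file path.
#' @return `path` (writer) / data.frame (reader).
#' @export
write_segments <- function(segments, path) {
  assert_that(all(c("onset_ms", "offset_ms") %in% names(segments)),
              "segments need onset_ms/offset_ms columns")
  write_tsv(segments, path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- read_tsv(path)
  assert_that(all(c("onset_ms", "offset_ms") %in% names(df)),
              sprintf("%s lacks onset_ms/offset_ms columns", path),
              "songeval_io_error")
  df
}

#' Write / read spike times (one ms value per line)
#'
#' @param spikes a [spike_train] or numeric vector (ms).
#' @param path file path.
#' @return `path` (writer) / numeric vector (reader).
#' @export
write_spike_times <- function(spikes, path) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  writeLines(fmt_num(st), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "songeval_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  x <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(x))
  if (length(bad)) {
    stop_songeval(sprintf("malformed spike time in %s at line %d: '%s'",
                          path, bad[1], lines[bad[1]]), "songeval_io_error")
  }
  x
}

#' Write / read event tables as TSV
#'
#' Columns `onset_ms` plus optional `offset_ms` and `kind`.
#'
#' @param events an [event_times].
#' @param path file path.
#' @return `path` (writer) / an [event_times] (reader).
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset_ms = events$onsets)
  if (!is.null(events$offsets)) df$offset_ms <- events$offsets
  df$kind <- events$kind
  write_tsv(df, path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  assert_that("onset_ms" %in% names(df),
              sprintf("%s lacks an onset_ms column", path), "songeval_io_error")
  event_times(df$onset_ms,
              offsets = if ("offset_ms" %in% names(df)) df$offset_ms,
              kind = if ("kind" %in% names(df)) df$kind[1] else "noise_burst")
}

#' Write / read antidromic trials as a TSV matrix
#'
#' First line is a comment header `# sample_rate_hz=<sr> stimulus_time_ms=<t>`;
#' the rest is one tab-separated trial per row.
#'
#' @param trials an [antidromic_trials].
#' @param path file path.
#' @return `path` (writer) / an [antidromic_trials] (reader).
#' @export
write_antidromic_trials <- function(trials, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%s stimulus_time_ms=%s",
                     fmt_num(trials$sample_rate),
                     fmt_num(trials$stimulus_time)), con)
  utils::write.table(trials$traces, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_antidromic_trials
#' @export
read_antidromic_trials <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "songeval_io_error")
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^# sample_rate_hz=([0-9.eE+-]+) stimulus_time_ms=([0-9.eE+-]+)", hdr))[[1]]
  assert_that(length(m) == 3,
              sprintf("%s line 1: missing sample-rate header", path),
              "songeval_io_error")
  mat <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(mat) <- NULL
  antidromic_trials(mat, as.numeric(m[2]), as.numeric(m[3]))
}
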