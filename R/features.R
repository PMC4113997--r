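# SAP-style acoustic features at 1 ms resolution.
#
# All features are computed from the multitaper spectrogram inside a fixed
# analysis band (default 860 Hz - 8.6 kHz), the band used throughout the
# package for similarity and stereotypy so every module sees the same
# spectral support.

default_band <- c(860, 8600)

#' Extract per-frame acoustic features from audio
#'
#' Computes, per 1 ms spectrogram frame: band amplitude (dB), frequency
#' modulation (degrees), Wiener entropy (log ratio of geometric to arithmetic
#' mean band power, always <= 0), pitch goodness (height of the cepstral
#' peak) and cepstral pitch (Hz).
#'
#' Frames are flagged silent when their band amplitude falls below an
#' absolute floor or more than `silence_rel_db` below the clip's loudest
#' frame (an amplitude gate, so low-level background noise in gaps counts as
#' silence just as digital zero does).  Flagged frames get the silence
#' convention: amplitude as measured, Wiener entropy 0, pitch goodness 0,
#' pitch 0 Hz; they are excluded from feature histograms and similarity
#' diagonals downstream.
#'
#' @param clip an [audio_clip], or a precomputed `spectrogram_mt`.
#' @param band analysis band in Hz (closed interval on bin centers).
#' @param pitch_range_hz search range for the cepstral pitch.
#' @param power_floor absolute linear-power floor used both as log regularizer
#'   and (times 10 x number of band bins) as the absolute silence threshold.
#' @param silence_rel_db frames this many dB below the clip's maximum band
#'   amplitude are flagged silent.
#' @param window_ms,step_ms,n_tapers,bandwidth_param spectrogram parameters,
#'   used when `clip` is raw audio.
#' @return a `feature_track`: list with `frame_times`, `amplitude`, `fm`,
#'   `wiener_entropy`, `pitch_goodness`, `pitch`, `silent` (logical), and
#'   `params`.
#' @export
extract_features <- function(clip, band = default_band,
                             pitch_range_hz = c(350, 4000),
                             power_floor = 1e-12, silence_rel_db = 45,
                             window_ms = 10, step_ms = 1, n_tapers = 2,
                             bandwidth_param = 1.5) {
  spec <- if (inherits(clip, "spectrogram_mt")) clip else
    compute_multitaper_spectrogram(clip, window_ms = window_ms,
                                   step_ms = step_ms, n_tapers = n_tapers,
                                   bandwidth_param = bandwidth_param)
  sr <- spec$params$sample_rate
  bins <- band_bins(spec$freqs, band)
  assert_that(length(bins) >= 3, "analysis band contains too few bins")
  pb <- spec$power[bins, , drop = FALSE]       # band power, bins x frames
  n_frames <- ncol(pb)

  band_sum <- colSums(pb)
  amplitude <- 10 * log10(band_sum + power_floor)
  silent <- band_sum < power_floor * length(bins) * 10 |
    amplitude < max(amplitude) - silence_rel_db

  # Wiener entropy: log(geometric mean / arithmetic mean); <= 0 by Jensen.
  le <- colMeans(log(pb + power_floor))
  la <- log(colMeans(pb) + power_floor)
  wiener <- pmin(le - la, 0)
  wiener[silent] <- 0

  # Cepstrum from the full (two-sided) log power spectrum of each frame.
  n_freq <- nrow(spec$power)
  win <- spec$params$sample_rate * spec$params$window_ms / 1000
  two_sided <- rbind(spec$power,
                     spec$power[(n_freq - 1):2, , drop = FALSE])
  cep <- Re(stats::mvfft(log(two_sided + power_floor), inverse = TRUE)) /
    nrow(two_sided)
  q_lo <- max(2L, ceiling(sr / pitch_range_hz[2]))
  q_hi <- min(nrow(cep) - 1L, floor(sr / pitch_range_hz[1]))
  assert_that(q_hi > q_lo, "pitch range unresolvable at this window length")
  cep_win <- cep[(q_lo:q_hi) + 1L, , drop = FALSE]   # row r+1 <-> lag r
  peak_row <- max.col(t(cep_win), ties.method = "first")
  pitch_goodness <- pmax(cep_win[cbind(peak_row, seq_len(n_frames))], 0)
  pitch <- sr / (q_lo + peak_row - 1)
  pitch[silent] <- 0
  pitch_goodness[silent] <- 0

  # FM: angle between temporal and spectral derivatives of band log power.
  lp <- log(pb + power_floor)
  if (n_frames >= 2) {
    dt <- cbind(lp[, 2:n_frames, drop = FALSE] -
                  lp[, 1:(n_frames - 1), drop = FALSE],
                lp[, n_frames] - lp[, n_frames - 1])
  } else {
    dt <- matrix(0, nrow(lp), 1)
  }
  df <- rbind(lp[2:nrow(lp), , drop = FALSE] -
                lp[1:(nrow(lp) - 1), , drop = FALSE], 0)
  fm <- atan2(sqrt(colMeans(dt^2)), sqrt(colMeans(df^2))) * 180 / pi
  fm[silent] <- 0

  structure(list(frame_times = spec$frame_times,
                 amplitude = amplitude, fm = fm, wiener_entropy = wiener,
                 pitch_goodness = pitch_goodness, pitch = pitch,
                 silent = silent,
                 params = c(spec$params, list(band = band,
                                              power_floor = power_floor))),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %d frames (%d silent), step %g ms\n",
              length(x$frame_times), sum(x$silent), x$params$step_ms))
  invisible(x)
}

n_frames <- function(track) length(track$frame_times)

#' Convert a feature track to a data frame
#'
#' @param x a `feature_track`.
#' @param ... unused.
#' @return a data.frame with one row per frame.
#' @export
as.data.frame.feature_track <- function(x, ...) {
  data.frame(time_ms = x$frame_times, amplitude = x$amplitude, fm = x$fm,
             wiener_entropy = x$wiener_entropy,
             pitch_goodness = x$pitch_goodness, pitch = x$pitch,
             silent = x$silent)
}

#' Segment syllables by amplitude gating
#'
#' Marks maximal runs of frames with amplitude >= threshold, merges silent
#' gaps shorter than `min_gap_ms`, and discards runs shorter than
#' `min_syllable_ms`.  Returned times are frame centers; intervals are
#' half-open `[onset, offset)`.
#'
#' @param track a `feature_track`.
#' @param threshold_db gate in dB.  `NULL` (default) uses the clip's noise
#'   floor (10th percentile of frame amplitude) + 12 dB.
#' @param min_syllable_ms minimum syllable duration retained.
#' @param min_gap_ms gaps shorter than this are bridged.
#' @return data.frame with columns `onset_ms`, `offset_ms`.
#' @export
segment_syllables <- function(track, threshold_db = NULL,
                              min_syllable_ms = 10, min_gap_ms = 5) {
  assert_that(inherits(track, "feature_track"), "track must be a feature_track")
  amp <- track$amplitude
  step <- track$params$step_ms
  if (is.null(threshold_db)) {
    threshold_db <- percentile(amp, 0.10) + 12
  }
  voiced <- amp >= threshold_db
  if (!any(voiced)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  # bridge short gaps
  r <- rle(voiced)
  gap_idx <- which(!r$values & r$lengths * step < min_gap_ms)
  gap_idx <- gap_idx[gap_idx > 1 & gap_idx < length(r$values)]
  if (length(gap_idx)) {
    r$values[gap_idx] <- TRUE
    voiced <- inverse.rle(r)
    r <- rle(voiced)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * step >= min_syllable_ms
  if (!any(keep)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  data.frame(onset_ms = track$frame_times[starts[keep]],
             offset_ms = track$frame_times[ends[keep]] + step)
}

#' Correlation between two feature distributions
#'
#' Histograms one feature of each track on a shared bin grid (silence-flagged
#' frames excluded), normalizes each histogram to unit mass, and returns the
#' Pearson correlation between the two histograms.
#'
#' @param track_a,track_b `feature_track`s.
#' @param feature_name one of `"amplitude"`, `"fm"`, `"wiener_entropy"`,
#'   `"pitch_goodness"`, `"pitch"`.
#' @param n_bins number of shared histogram bins.
#' @return Pearson correlation in \[-1, 1\].
#' @export
feature_distribution_correlation <- function(track_a, track_b, feature_name,
                                             n_bins = 50) {
  features <- c("amplitude", "fm", "wiener_entropy", "pitch_goodness", "pitch")
  assert_that(feature_name %in% features,
              sprintf("unknown feature '%s'", feature_name))
  va <- track_a[[feature_name]][!track_a$silent]
  vb <- track_b[[feature_name]][!track_b$silent]
  assert_that(length(va) > 0 && length(vb) > 0,
              "both tracks must have non-silent frames")
  rng <- range(c(va, vb))
  if (diff(rng) == 0) {
    stop_songeval("feature values are constant; histogram correlation undefined",
                  "songeval_degenerate_error")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ha <- tabulate(findInterval(va, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins)
  hb <- tabulate(findInterval(vb, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins)
  ha <- ha / sum(ha)
  hb <- hb / sum(hb)
  if (stats::sd(ha) == 0 || stats::sd(hb) == 0) {
    stop_songeval("degenerate single-bin histogram; correlation undefined",
                  "songeval_degenerate_error")
  }
  stats::cor(ha, hb)
}
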