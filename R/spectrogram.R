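# Multitaper spectrogram.  Defaults follow the standard song-stereotypy
# settings: k = 2 DPSS tapers with time-bandwidth parameter 1.5, 10 ms
# analysis window, 1 ms step.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, via the eigenvectors of the classic symmetric tridiagonal
#' matrix whose eigenvectors coincide with the Slepian sequences.  Tapers are
#' unit-energy; sign is fixed so each taper has non-negative mean (even
#' orders) or a non-negative leading slope (odd orders).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (dimensionless).
#' @param k number of tapers.
#' @return an `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 1.5, k = 2) {
  assert_that(is_count(n) && n >= 2, "n must be an integer >= 2")
  assert_that(is_count(k) && k < n, "k must be a positive integer < n")
  assert_that(nw > 0 && nw < n / 2, "nw must be in (0, n/2)")
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- diag(diag_main)
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(m, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {
      # odd-order tapers integrate to ~0; fix sign by the leading lobe
      if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
    }
  }
  tap
}

#' Multitaper spectrogram of an audio clip
#'
#' Slides a `window_ms` window in `step_ms` steps; within each window the
#' power spectrum is the average of `n_tapers` DPSS eigenspectra.  Frame
#' timestamps are window centers, in ms from clip start.
#'
#' @param clip an [audio_clip].
#' @param window_ms analysis window length (ms).
#' @param step_ms hop between frames (ms).
#' @param n_tapers number of DPSS tapers averaged.
#' @param bandwidth_param DPSS time-bandwidth product.
#' @return an object of class `spectrogram_mt` with elements `power`
#'   (frequency x time matrix, linear power), `frame_times` (ms), `freqs`
#'   (Hz) and `params`.
#' @export
compute_multitaper_spectrogram <- function(clip, window_ms = 10, step_ms = 1,
                                           n_tapers = 2,
                                           bandwidth_param = 1.5) {
  assert_that(inherits(clip, "audio_clip"), "clip must be an audio_clip")
  sr <- clip$sample_rate
  win <- as.integer(round(window_ms * sr / 1000))
  step <- as.integer(round(step_ms * sr / 1000))
  assert_that(win >= 2 && step >= 1, "window/step too short for sample rate")
  n <- length(clip$samples)
  if (n < win) {
    stop_songeval(sprintf("clip (%d samples) shorter than one %d-sample window",
                          n, win), "songeval_length_error")
  }
  n_frames <- (n - win) %/% step + 1L
  starts <- (seq_len(n_frames) - 1L) * step
  idx <- outer(seq_len(win), starts, `+`)   # win x n_frames sample indices
  frames <- matrix(clip$samples[idx], nrow = win)
  tapers <- dpss_tapers(win, nw = bandwidth_param, k = n_tapers)
  n_freq <- win %/% 2 + 1L
  power <- matrix(0, nrow = n_freq, ncol = n_frames)
  for (j in seq_len(n_tapers)) {
    ft <- stats::mvfft(frames * tapers[, j])
    power <- power + (Mod(ft[seq_len(n_freq), , drop = FALSE])^2) / n_tapers
  }
  structure(list(
    power = power,
    frame_times = (starts + win / 2) * 1000 / sr,
    freqs = (seq_len(n_freq) - 1L) * sr / win,
    params = list(n_tapers = n_tapers, bandwidth_param = bandwidth_param,
                  window_ms = window_ms, step_ms = step_ms,
                  sample_rate = sr)),
    class = "spectrogram_mt")
}

#' @export
print.spectrogram_mt <- function(x, ...) {
  cat(sprintf("<spectrogram_mt> %d freq bins x %d frames, %g-%g Hz, step %g ms\n",
              nrow(x$power), ncol(x$power), min(x$freqs), max(x$freqs),
              x$params$step_ms))
  invisible(x)
}

# Indices of frequency bins whose centers fall in the closed band [lo, hi] Hz.
band_bins <- function(freqs, band) {
  which(freqs >= band[1] & freqs <= band[2])
}
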