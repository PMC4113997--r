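# Antidromic response significance: band power of the averaged evoked
# trace in a short post-stimulus window, tested against no-response sites.

#' Antidromic trial set
#'
#' @param traces trial x time voltage matrix (>= 2 trials).
#' @param sample_rate Hz.
#' @param stimulus_time_ms stimulus onset within each trace (ms).
#' @return an `antidromic_trials` object.
#' @export
antidromic_trials <- function(traces, sample_rate, stimulus_time_ms = 0) {
  traces <- as.matrix(traces)
  assert_that(nrow(traces) >= 2, "need >= 2 trials")
  assert_that(sample_rate > 0, "sample_rate must be positive")
  trace_ms <- 1000 * ncol(traces) / sample_rate
  assert_that(stimulus_time_ms >= 0 && stimulus_time_ms + 17 <= trace_ms,
              "traces must span at least 17 ms beyond the stimulus")
  structure(list(traces = traces, sample_rate = sample_rate,
                 stimulus_time = stimulus_time_ms),
            class = "antidromic_trials")
}

#' Band power of an averaged evoked trace
#'
#' Averages the given trials, extracts the `window_ms` post-stimulus
#' segment, computes its single-taper (rectangular-window) periodogram, and
#' sums power over DFT bins whose frequencies fall in `band_hz` (closed, on
#' the one-sided grid).
#'
#' @param trials an [antidromic_trials] or a plain trial x time matrix
#'   paired with `sample_rate`/`stimulus_time_ms`.
#' @param window_ms post-stimulus window, default `c(2, 17)`.
#' @param band_hz frequency band, default `c(200, 2000)`.
#' @param sample_rate,stimulus_time_ms used when `trials` is a bare matrix.
#' @return band power (scalar).
#' @export
evoked_band_power <- function(trials, window_ms = c(2, 17),
                              band_hz = c(200, 2000),
                              sample_rate = NULL, stimulus_time_ms = 0) {
  if (!inherits(trials, "antidromic_trials")) {
    trials <- antidromic_trials(trials, sample_rate, stimulus_time_ms)
  }
  sr <- trials$sample_rate
  avg <- colMeans(trials$traces)
  i0 <- as.integer(round((trials$stimulus_time + window_ms[1]) * sr / 1000)) + 1L
  i1 <- as.integer(round((trials$stimulus_time + window_ms[2]) * sr / 1000))
  assert_that(i0 >= 1 && i1 <= length(avg) && i1 > i0,
              "analysis window exceeds trace span")
  x <- avg[i0:i1]
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (0:(n %/% 2)) * sr / n
  sum(p[seq_along(freqs)][freqs >= band_hz[1] & freqs <= band_hz[2]])
}

#' Significance of an antidromic response
#'
#' Tests whether the 200 Hz-2 kHz band power of the averaged response in
#' the 2-17 ms post-stimulus window is higher at the candidate site than at
#' no-response reference sites (one-sided Welch t-test on band powers).
#'
#' Each argument may be a list of [antidromic_trials] (one band power per
#' site) or a single trial set, in which case its trials are partitioned
#' into `n_split` disjoint sub-averages to provide replicate band powers.
#'
#' @param trials candidate site(s).
#' @param reference no-response site(s).
#' @param window_ms,band_hz analysis window and band.
#' @param n_split sub-averages per single trial set.
#' @return list with `p_value`, `statistic`, `trial_powers`,
#'   `reference_powers`.
#' @export
antidromic_significance <- function(trials, reference, window_ms = c(2, 17),
                                    band_hz = c(200, 2000), n_split = 8) {
  powers <- function(x) {
    if (inherits(x, "antidromic_trials")) x <- split_trials(x, n_split)
    assert_that(is.list(x) && length(x) >= 2,
                "need >= 2 band-power replicates per group")
    vapply(x, evoked_band_power, numeric(1),
           window_ms = window_ms, band_hz = band_hz)
  }
  bp_t <- powers(trials)
  bp_r <- powers(reference)
  tt <- stats::t.test(bp_t, bp_r, alternative = "greater", var.equal = FALSE)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       trial_powers = bp_t, reference_powers = bp_r)
}

# Deterministic partition of one trial set into n_split sub-sets of >= 2
# trials each (contiguous blocks, trial order preserved).
split_trials <- function(set, n_split) {
  n <- nrow(set$traces)
  n_split <- max(2L, min(as.integer(n_split), n %/% 2L))
  grp <- cut(seq_len(n), n_split, labels = FALSE)
  lapply(seq_len(n_split), function(g)
    antidromic_trials(set$traces[grp == g, , drop = FALSE],
                      set$sample_rate, set$stimulus_time))
}
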