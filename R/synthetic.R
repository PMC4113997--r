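# Synthetic songs and spike trains with known ground truth.
#
# Songs are built from harmonic-stack syllables (fundamental + 1/h harmonic
# rolloff, optional linear FM sweep, raised-cosine edges) separated by
# silent gaps, repeated as motifs within a bout.  A distortion spec injects
# tutor->pupil differences (pitch/duration jitter, syllable drops, sequence
# shuffles, additive noise) at known magnitudes.  Spike trains are
# inhomogeneous Poisson processes: a constant baseline plus a rectangular
# rate increment of known latency, amplitude and duration after each event,
# which makes latency/duration ground truth unambiguous for recovery tests.

#' Song template
#'
#' @param syllables list of syllable descriptors, each with `f0` (Hz),
#'   `n_harmonics`, `duration_ms`, `fm_sweep` (Hz/ms) and `amplitude_db`
#'   (dB relative to the 0.3 full-scale reference).
#' @param gaps_ms silent gaps between consecutive syllables (length
#'   `length(order) - 1`, recycled).
#' @param order motif order as indices into `syllables`.
#' @return a `song_template`.
#' @export
song_template <- function(syllables = NULL, gaps_ms = c(35, 45),
                          order = NULL) {
  if (is.null(syllables)) {
    syllables <- list(
      list(f0 = 620,  n_harmonics = 4, duration_ms = 85,  fm_sweep = 1.5,
           amplitude_db = 0),
      list(f0 = 980,  n_harmonics = 5, duration_ms = 60,  fm_sweep = -3,
           amplitude_db = 0),
      list(f0 = 1420, n_harmonics = 3, duration_ms = 110, fm_sweep = 0.5,
           amplitude_db = -3))
  }
  assert_that(length(syllables) >= 1, "need >= 1 syllable")
  for (s in syllables) {
    assert_that(all(c("f0", "n_harmonics", "duration_ms") %in% names(s)) &&
                  s$duration_ms > 0 && s$f0 > 0,
                "each syllable needs positive f0 and duration_ms")
  }
  order <- order %||% seq_along(syllables)
  structure(list(syllables = syllables, gaps_ms = gaps_ms, order = order),
            class = "song_template")
}

#' Distortion specification
#'
#' A scalar `level` maps onto the continuous knobs (level 0 = exact copy):
#' `pitch_jitter_sd = 0.08 * level`, `duration_jitter_sd = 0.12 * level`,
#' additive noise at `-55 + 30 * level` dB (none at level 0).  Any knob can
#' also be set explicitly.
#'
#' @param level scalar distortion level in \[0, 1\] (may exceed 1).
#' @param pitch_jitter_sd per-rendition fractional SD of each syllable's f0.
#' @param duration_jitter_sd per-rendition fractional SD of duration.
#' @param syllable_drop_prob probability a rendition is silently dropped.
#' @param sequence_shuffle_prob probability a motif's syllable order is
#'   randomly permuted.
#' @param additive_noise_db white-noise level in dB re the syllable
#'   reference amplitude; `-Inf` for none.
#' @param seed default RNG seed carried with the spec.
#' @return a `distortion_spec`.
#' @export
distortion_spec <- function(level = 0, pitch_jitter_sd = NULL,
                            duration_jitter_sd = NULL,
                            syllable_drop_prob = 0,
                            sequence_shuffle_prob = 0,
                            additive_noise_db = NULL, seed = NULL) {
  assert_that(level >= 0, "level must be >= 0")
  assert_that(syllable_drop_prob >= 0 && syllable_drop_prob <= 1 &&
                sequence_shuffle_prob >= 0 && sequence_shuffle_prob <= 1,
              "probabilities must be in [0, 1]")
  structure(list(
    level = level,
    pitch_jitter_sd = pitch_jitter_sd %||% (0.08 * level),
    duration_jitter_sd = duration_jitter_sd %||% (0.12 * level),
    syllable_drop_prob = syllable_drop_prob,
    sequence_shuffle_prob = sequence_shuffle_prob,
    additive_noise_db = additive_noise_db %||%
      (if (level > 0) -55 + 30 * level else -Inf),
    seed = seed), class = "distortion_spec")
}

ref_amplitude <- 0.3

syllable_wave <- function(f0, n_harmonics, duration_ms, fm_sweep,
                          amplitude_db, sample_rate, edge_ms = 5) {
  n <- max(8L, as.integer(round(duration_ms * sample_rate / 1000)))
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  f_inst <- pmax(f0 + (fm_sweep %||% 0) * t_ms, 20)
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) x <- x + sin(h * phase) / h
  ne <- min(as.integer(edge_ms * sample_rate / 1000), n %/% 2)
  if (ne > 1) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(ne) - 1) / (ne - 1)))
    x[1:ne] <- x[1:ne] * ramp
    x[(n - ne + 1):n] <- x[(n - ne + 1):n] * rev(ramp)
  }
  x / max(abs(x)) * ref_amplitude * 10^((amplitude_db %||% 0) / 20)
}

#' Generate synthetic song bouts with ground truth
#'
#' Each bout is an introductory silence, then `n_motifs` motif renditions
#' (syllables + gaps from the template) separated by an inter-motif gap,
#' then a trailing silence.  Distortion is applied per rendition.  At
#' distortion level 0 every bout is sample-identical to the undistorted
#' template rendering.
#'
#' @param template a [song_template].
#' @param distortion a [distortion_spec].
#' @param n_bouts number of bouts.
#' @param n_motifs motif renditions per bout.
#' @param sample_rate Hz.
#' @param intro_ms,intermotif_gap_ms,trail_ms bout framing silences (ms).
#' @param seed RNG seed (defaults to `distortion$seed`).
#' @return list with `bouts` (list of [audio_clip]), `segments` (per bout, a
#'   data.frame `onset_ms`/`offset_ms`/`syllable_index`), `template`,
#'   `distortion`, `sample_rate`.
#' @export
generate_song <- function(template = song_template(),
                          distortion = distortion_spec(0), n_bouts = 1,
                          n_motifs = 3, sample_rate = 40000, intro_ms = 50,
                          intermotif_gap_ms = 120, trail_ms = 50,
                          seed = NULL) {
  assert_that(inherits(template, "song_template"), "template must be a song_template")
  assert_that(inherits(distortion, "distortion_spec"),
              "distortion must be a distortion_spec")
  seed <- seed %||% distortion$seed
  with_seed(seed, {
    bouts <- vector("list", n_bouts)
    segments <- vector("list", n_bouts)
    gaps <- rep_len(template$gaps_ms, max(1, length(template$order) - 1))
    for (b in seq_len(n_bouts)) {
      wave <- numeric(as.integer(intro_ms * sample_rate / 1000))
      segs <- list()
      for (m in seq_len(n_motifs)) {
        ord <- template$order
        if (distortion$sequence_shuffle_prob > 0 &&
              stats::runif(1) < distortion$sequence_shuffle_prob) {
          ord <- sample(ord)
        }
        for (k in seq_along(ord)) {
          s <- template$syllables[[ord[k]]]
          f0 <- s$f0
          dur <- s$duration_ms
          if (distortion$pitch_jitter_sd > 0) {
            f0 <- f0 * max(0.3, 1 + stats::rnorm(1, 0, distortion$pitch_jitter_sd))
          }
          if (distortion$duration_jitter_sd > 0) {
            dur <- dur * max(0.25, 1 + stats::rnorm(1, 0, distortion$duration_jitter_sd))
          }
          dropped <- distortion$syllable_drop_prob > 0 &&
            stats::runif(1) < distortion$syllable_drop_prob
          if (!dropped) {
            w <- syllable_wave(f0, s$n_harmonics, dur, s$fm_sweep,
                               s$amplitude_db, sample_rate)
            onset <- 1000 * length(wave) / sample_rate
            wave <- c(wave, w)
            segs[[length(segs) + 1L]] <- data.frame(
              onset_ms = onset,
              offset_ms = onset + 1000 * length(w) / sample_rate,
              syllable_index = ord[k])
          }
          gap <- if (k < length(ord)) gaps[k] else intermotif_gap_ms
          wave <- c(wave, numeric(as.integer(gap * sample_rate / 1000)))
        }
      }
      wave <- c(wave, numeric(as.integer(trail_ms * sample_rate / 1000)))
      if (is.finite(distortion$additive_noise_db)) {
        wave <- wave + stats::rnorm(length(wave)) * ref_amplitude *
          10^(distortion$additive_noise_db / 20)
      }
      bouts[[b]] <- audio_clip(wave, sample_rate)
      segments[[b]] <- if (length(segs)) do.call(rbind, segs) else
        data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                   syllable_index = integer(0))
    }
    list(bouts = bouts, segments = segments, template = template,
         distortion = distortion, sample_rate = sample_rate)
  })
}

#' Tutor motif from an undistorted template rendering
#'
#' Renders one motif (no distortion, no noise), extracts features and
#' returns a [tutor_motif] with exact syllable boundaries.
#'
#' @param template a [song_template].
#' @param sample_rate Hz.
#' @param ... passed to [extract_features()].
#' @return a [tutor_motif].
#' @export
template_motif <- function(template = song_template(), sample_rate = 40000,
                           ...) {
  g <- generate_song(template, distortion_spec(0), n_bouts = 1, n_motifs = 1,
                     sample_rate = sample_rate, intro_ms = 0,
                     intermotif_gap_ms = 0, trail_ms = 0)
  track <- extract_features(g$bouts[[1]], ...)
  tutor_motif(track, g$segments[[1]][, c("onset_ms", "offset_ms")])
}

#' Response specification for synthetic spike trains
#'
#' @param baseline_rate baseline firing rate (Hz, >= 0).
#' @param latency_ms response onset after each event (ms).
#' @param amplitude rate increment during the response (Hz; may be negative
#'   down to `-baseline_rate`).
#' @param duration_ms response duration (ms).
#' @param jitter_sd_ms per-event Gaussian jitter of the response onset.
#' @param seed default RNG seed carried with the spec.
#' @return a `response_spec`.
#' @export
response_spec <- function(baseline_rate = 5, latency_ms = 24, amplitude = 60,
                          duration_ms = 90, jitter_sd_ms = 0, seed = NULL) {
  assert_that(baseline_rate >= 0, "baseline_rate must be >= 0")
  if (baseline_rate + amplitude < 0) {
    stop_songeval("negative instantaneous rate: baseline + amplitude < 0",
                  "songeval_validation_error")
  }
  structure(list(baseline_rate = baseline_rate, latency_ms = latency_ms,
                 amplitude = amplitude, duration_ms = duration_ms,
                 jitter_sd_ms = jitter_sd_ms, seed = seed),
            class = "response_spec")
}

#' Generate an inhomogeneous Poisson spike train
#'
#' Baseline homogeneous Poisson activity over `[0, span_ms]` plus a
#' rectangular rate increment of `spec$amplitude` Hz from
#' `latency` to `latency + duration` after each event onset (negative
#' amplitudes thin the baseline inside the window).
#'
#' @param events an [event_times] or numeric onset vector (ms).
#' @param spec a [response_spec].
#' @param span_ms recording span (ms).
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return a [spike_train].
#' @export
generate_spike_train <- function(events, spec = response_spec(),
                                 span_ms, seed = NULL) {
  onsets <- if (inherits(events, "event_times")) events$onsets else
    as.numeric(events)
  assert_that(all(onsets >= 0 & onsets <= span_ms), "events must lie in span")
  seed <- seed %||% spec$seed
  with_seed(seed, {
    n_base <- stats::rpois(1, spec$baseline_rate * span_ms / 1000)
    st <- stats::runif(n_base, 0, span_ms)
    w0 <- onsets + spec$latency_ms +
      if (spec$jitter_sd_ms > 0) stats::rnorm(length(onsets), 0, spec$jitter_sd_ms)
      else 0
    w1 <- w0 + spec$duration_ms
    if (spec$amplitude > 0) {
      extra <- unlist(lapply(seq_along(onsets), function(i) {
        k <- stats::rpois(1, spec$amplitude * spec$duration_ms / 1000)
        stats::runif(k, w0[i], w1[i])
      }))
      st <- c(st, extra)
    } else if (spec$amplitude < 0) {
      p_keep <- 1 + spec$amplitude / max(spec$baseline_rate, 1e-12)
      inwin <- vapply(st, function(t) any(t >= w0 & t < w1), logical(1))
      drop <- inwin & stats::runif(length(st)) > p_keep
      st <- st[!drop]
    }
    st <- sort(st[st >= 0 & st <= span_ms])
    dup <- which(diff(st) <= 0)
    while (length(dup)) {   # enforce strict increase after rare exact ties
      st[dup + 1L] <- st[dup + 1L] + 1e-9
      st <- sort(st)
      dup <- which(diff(st) <= 0)
    }
    spike_train(st, c(0, span_ms))
  })
}

#' Regularly spaced noise-burst events
#'
#' @param n_events number of events.
#' @param interval_ms spacing between onsets.
#' @param start_ms first onset.
#' @param duration_ms burst duration (offsets = onsets + duration).
#' @return an [event_times] of kind `"noise_burst"`.
#' @export
noise_burst_events <- function(n_events, interval_ms = 2500,
                               start_ms = 1500, duration_ms = 50) {
  onsets <- start_ms + (seq_len(n_events) - 1) * interval_ms
  event_times(onsets, onsets + duration_ms, kind = "noise_burst")
}

#' Generate synthetic antidromic stimulation trials
#'
#' Gaussian noise traces with an optional damped sinusoid added after the
#' stimulus, emulating an evoked antidromic population response.
#'
#' @param n_trials number of trials.
#' @param signal `NULL` for noise only, or a list with `freq_hz`,
#'   `amplitude`, `onset_ms` (post-stimulus), `decay_ms`.
#' @param noise_sd per-sample Gaussian noise SD.
#' @param sample_rate Hz.
#' @param trace_ms trace duration.
#' @param stimulus_time_ms stimulus onset within the trace.
#' @param seed RNG seed.
#' @return an [antidromic_trials].
#' @export
generate_antidromic_trials <- function(n_trials = 16, signal = NULL,
                                       noise_sd = 1, sample_rate = 40000,
                                       trace_ms = 25, stimulus_time_ms = 0,
                                       seed = NULL) {
  n <- as.integer(round(trace_ms * sample_rate / 1000))
  with_seed(seed, {
    traces <- matrix(stats::rnorm(n_trials * n, 0, noise_sd),
                     nrow = n_trials)
    if (!is.null(signal)) {
      t_ms <- (seq_len(n) - 1) / sample_rate * 1000 - stimulus_time_ms
      rel <- t_ms - signal$onset_ms
      s <- ifelse(rel >= 0,
                  signal$amplitude * exp(-rel / signal$decay_ms) *
                    sin(2 * pi * signal$freq_hz * rel / 1000), 0)
      assert_that(signal$onset_ms >= 0 && signal$onset_ms < trace_ms,
                  "signal onset must lie within the trace")
      traces <- sweep(traces, 2, s, `+`)
    }
    antidromic_trials(traces, sample_rate, stimulus_time_ms)
  })
}
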