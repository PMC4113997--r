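# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (explicit loops, textbook definitions) so they stay independent of the
# package's vectorized implementations.

SR <- 40000

tone_clip <- function(freq_hz, dur_s = 0.5, amp = 0.3, sr = SR) {
  audio_clip(amp * sin(2 * pi * freq_hz * (0:(dur_s * sr - 1)) / sr), sr)
}

noise_clip <- function(dur_s = 0.5, sd = 0.1, sr = SR, seed = 1) {
  set.seed(seed)
  audio_clip(stats::rnorm(dur_s * sr, 0, sd), sr)
}

harmonic_clip <- function(f0, n_harm = 5, dur_s = 0.3, sr = SR) {
  t <- (0:(dur_s * sr - 1)) / sr
  x <- 0
  for (h in 1:n_harm) x <- x + sin(2 * pi * h * f0 * t) / h
  audio_clip(0.3 * x / max(abs(x)), sr)
}

# Hand-built feature track: one row per frame, frame centers at 0.5, 1.5, ...
make_track <- function(df, step_ms = 1, silent = NULL) {
  n <- nrow(df)
  structure(list(
    frame_times = (seq_len(n) - 1) * step_ms + step_ms / 2,
    amplitude = df$amplitude %||% rep(0, n),
    fm = df$fm, wiener_entropy = df$wiener_entropy,
    pitch_goodness = df$pitch_goodness, pitch = df$pitch,
    silent = silent %||% rep(FALSE, n),
    params = list(step_ms = step_ms, window_ms = step_ms, sample_rate = SR,
                  band = c(860, 8600), power_floor = 1e-12)),
    class = "feature_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Constant-feature track built from per-frame labels; distinct labels get
# well separated feature vectors, label 0 is a gap (zeros).
label_track <- function(labels, step_ms = 1) {
  base <- rbind(c(0, 0, 0, 0),
                c(20, -3, 5, 600), c(60, -6, 9, 1000), c(40, -9, 3, 1500),
                c(80, -1, 7, 800), c(10, -8, 2, 2500))
  f <- base[labels + 1L, , drop = FALSE]
  make_track(data.frame(amplitude = ifelse(labels == 0, -60, 0),
                        fm = f[, 1], wiener_entropy = f[, 2],
                        pitch_goodness = f[, 3], pitch = f[, 4]),
             step_ms = step_ms)
}

# Naive similarity-matrix oracle: explicit double loop over frame pairs.
naive_similarity <- function(tutor, pupil, tau,
                             features = c("fm", "wiener_entropy",
                                          "pitch_goodness", "pitch")) {
  a <- sapply(features, function(f) tutor[[f]])
  b <- sapply(features, function(f) pupil[[f]])
  ref <- a[!tutor$silent, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  m <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum(((a[i, ] - mu) / sdv - (b[j, ] - mu) / sdv)^2))
      m[i, j] <- exp(-d / tau)
    }
  }
  m
}

# Exhaustive placement oracle: for each tutor syllable, try every section
# and offset; plain mean along the diagonal (tracks used with the oracle
# must have no silent pupil frames so the silence rule is inert).
exhaustive_match <- function(motif, sections, sim) {
  syl <- motif$syllables
  out <- NULL
  for (s in seq_len(nrow(syl))) {
    fr <- which(motif$track$frame_times >= syl$onset_ms[s] &
                  motif$track$frame_times < syl$offset_ms[s])
    len <- length(fr)
    best <- list(score = -Inf)
    for (sec in seq_len(nrow(sections))) {
      for (off in 0:(sections$end_frame[sec] - sections$start_frame[sec] -
                       len + 1)) {
        p <- sections$start_frame[sec] + off
        if (p + len - 1 > ncol(sim$values)) next
        sc <- mean(sim$values[cbind(fr, p:(p + len - 1))])
        if (sc > best$score) {
          best <- list(score = sc, section = sec, offset = off, p = p)
        }
      }
    }
    out <- rbind(out, data.frame(syllable = s, section = best$section,
                                 offset = best$offset, p = best$p,
                                 score = best$score))
  }
  out
}

# Naive peak-lag spectrogram correlation: textbook loops.
naive_spec_similarity <- function(a, b, band = c(860, 8600),
                                  min_overlap_frac = 0.5) {
  bins <- which(a$freqs >= band[1] & a$freqs <= band[2])
  pa <- a$power[bins, , drop = FALSE]
  pb <- b$power[bins, , drop = FALSE]
  na <- ncol(pa); nb <- ncol(pb)
  best <- -Inf
  for (lag in (-(na - 1)):(nb - 1)) {
    vals <- c()
    for (i in seq_len(na)) {
      j <- i + lag
      if (j < 1 || j > nb) next
      if (stats::sd(pa[, i]) == 0 || stats::sd(pb[, j]) == 0) next
      vals <- c(vals, stats::cor(pa[, i], pb[, j]))
    }
    if (length(vals) >= max(1, min_overlap_frac * min(na, nb)) &&
          mean(vals) > best) {
      best <- mean(vals)
    }
  }
  best
}

# Direct DFT band power of the averaged trace: textbook O(n^2) DFT.
naive_band_power <- function(trials, window_ms = c(2, 17),
                             band = c(200, 2000)) {
  avg <- colMeans(trials$traces)
  sr <- trials$sample_rate
  i0 <- round((trials$stimulus_time + window_ms[1]) * sr / 1000) + 1
  i1 <- round((trials$stimulus_time + window_ms[2]) * sr / 1000)
  x <- avg[i0:i1]
  n <- length(x)
  total <- 0
  for (k in 0:(n %/% 2)) {
    f <- k * sr / n
    if (f >= band[1] && f <= band[2]) {
      re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
      total <- total + (re^2 + im^2) / n
    }
  }
  total
}

# One-syllable template used by stereotypy fixtures.
mono_template <- function(f0 = 800, dur = 70, fm = 2) {
  song_template(list(list(f0 = f0, n_harmonics = 4, duration_ms = dur,
                          fm_sweep = fm, amplitude_db = 0)),
                gaps_ms = 0, order = 1)
}

syllable_db <- function(n, jitter = 0, noise_db = -45, seed = 1,
                        template = mono_template()) {
  g <- generate_song(template,
                     distortion_spec(0, pitch_jitter_sd = jitter,
                                     duration_jitter_sd = jitter,
                                     additive_noise_db = noise_db),
                     n_bouts = n, n_motifs = 1, intro_ms = 0,
                     intermotif_gap_ms = 0, trail_ms = 0, seed = seed)
  g$bouts
}
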