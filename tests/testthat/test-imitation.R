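# Imitation scoring: similarity matrix, sectioning, syllable placement,
# sequence score, composite score and capacity rescaling.

test_that("similarity matrix matches a brute-force pairwise oracle", {
  set.seed(31)
  feats <- function(n) data.frame(fm = stats::runif(n, 0, 90),
                                  wiener_entropy = stats::runif(n, -8, 0),
                                  pitch_goodness = stats::runif(n, 0, 10),
                                  pitch = stats::runif(n, 400, 2000))
  tutor <- make_track(feats(3))
  pupil <- make_track(feats(3))
  sim <- build_similarity_matrix(tutor, pupil, tau = 1.5)
  expect_equal(sim$values, naive_similarity(tutor, pupil, 1.5),
               tolerance = 1e-12)

  # self-comparison: unit diagonal; all entries within [0, 1]
  self <- build_similarity_matrix(tutor, tutor, tau = 1.5)
  expect_equal(diag(self$values), rep(1, 3))
  big_a <- make_track(feats(40)); big_b <- make_track(feats(60))
  v <- build_similarity_matrix(big_a, big_b, tau = 0.8)$values
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
})

test_that("pupil sectioning yields 2x-motif sections with a right-aligned tail", {
  pupil <- label_track(rep(1, 400))    # 400 frames at 1 ms
  s1 <- section_pupil(pupil, tutor_duration_ms = 200)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$end_frame - s1$start_frame + 1L, 400L)

  # 5 s bout, 1 s motif, stride = motif duration: floor((5-2)/1)+1 sections
  pupil5 <- label_track(rep(1, 5000))
  s5 <- section_pupil(pupil5, tutor_duration_ms = 1000)
  expect_equal(nrow(s5), floor((5000 - 2000) / 1000) + 1L)
  expect_true(all(s5$end_frame - s5$start_frame + 1L == 2000L))

  # non-flush bout gains one right-aligned boundary section
  pupil53 <- label_track(rep(1, 5300))
  s53 <- section_pupil(pupil53, tutor_duration_ms = 1000)
  expect_equal(nrow(s53), 5L)
  expect_equal(s53$end_frame[5], 5300L)

  expect_error(section_pupil(label_track(rep(1, 100)), 200),
               class = "songeval_short_bout_error")
})

test_that("syllable placement equals the exhaustive enumeration oracle", {
  set.seed(32)
  for (rep in 1:6) {
    n_syl <- sample(1:5, 1)
    lens <- sample(4:9, n_syl, replace = TRUE)
    gaps <- sample(2:5, n_syl, replace = TRUE)
    labels <- integer(0)
    onsets <- offsets <- numeric(0)
    for (s in seq_len(n_syl)) {
      onsets <- c(onsets, length(labels))
      labels <- c(labels, rep(s, lens[s]))
      offsets <- c(offsets, length(labels))
      labels <- c(labels, rep(0L, gaps[s]))
    }
    tutor <- make_track(data.frame(
      fm = stats::runif(length(labels), 0, 90),
      wiener_entropy = stats::runif(length(labels), -8, 0),
      pitch_goodness = stats::runif(length(labels), 0, 10),
      pitch = stats::runif(length(labels), 400, 2000)))
    motif <- tutor_motif(tutor, data.frame(onset_ms = onsets,
                                           offset_ms = offsets))
    np <- sample((2 * length(labels)):(4 * length(labels)), 1)
    pupil <- make_track(data.frame(
      fm = stats::runif(np, 0, 90),
      wiener_entropy = stats::runif(np, -8, 0),
      pitch_goodness = stats::runif(np, 0, 10),
      pitch = stats::runif(np, 400, 2000)))
    sim <- build_similarity_matrix(tutor, pupil, tau = 1.2)
    sections <- section_pupil(pupil, motif$duration_ms)
    expect_lte(nrow(sections), 3L)
    got <- match_syllables(motif, sections, sim)
    want <- exhaustive_match(motif, sections, sim)
    expect_equal(got$matches$pupil_section_index, want$section)
    expect_equal(got$matches$global_start_frame, want$p)
    expect_equal(got$matches$acoustic_similarity, want$score,
                 tolerance = 1e-9)
    w <- offsets - onsets
    expect_equal(got$acoustic_score,
                 sum(want$score * w) / sum(w), tolerance = 1e-9)
  }
})

test_that("an exact motif copy scores acoustic = sequence = 1 at the copy position", {
  tutor_labels <- c(rep(1, 8), rep(0, 3), rep(2, 6), rep(0, 3), rep(3, 9))
  tutor <- label_track(tutor_labels)
  motif <- tutor_motif(tutor, data.frame(onset_ms = c(0, 11, 20),
                                         offset_ms = c(8, 17, 29)))
  copy_at <- 20L
  pupil <- label_track(c(rep(0, copy_at), tutor_labels, rep(0, 25)))
  sim <- build_similarity_matrix(tutor, pupil, tau = 1.5)
  sections <- section_pupil(pupil, motif$duration_ms)
  m <- match_syllables(motif, sections, sim)
  expect_equal(m$acoustic_score, 1.0)
  expect_equal(m$matches$global_start_frame, copy_at + c(1L, 12L, 21L))
  expect_equal(as.numeric(sequence_score(motif, m$matches, sim)), 1.0)
})

test_that("reversed syllable order keeps acoustic = 1 but drops the sequence score", {
  syl <- function(lab, len) rep(lab, len)
  gap <- rep(0, 4)
  tutor <- label_track(c(syl(1, 8), gap, syl(2, 8), gap, syl(3, 8)))
  motif <- tutor_motif(tutor, data.frame(onset_ms = c(0, 12, 24),
                                         offset_ms = c(8, 20, 32)))
  pupil <- label_track(c(rep(0, 10), syl(3, 8), gap, syl(2, 8), gap,
                         syl(1, 8), rep(0, 30)))
  sim <- build_similarity_matrix(tutor, pupil, tau = 1.5)
  m <- match_syllables(motif, section_pupil(pupil, motif$duration_ms), sim)
  expect_equal(m$acoustic_score, 1.0)
  expect_lt(as.numeric(sequence_score(motif, m$matches, sim)), 0.5)
})

test_that("sequence score equals the manual flanking-segment enumeration", {
  tutor_labels <- c(rep(1, 6), rep(0, 3), rep(2, 5), rep(0, 2), rep(3, 7))
  tutor <- label_track(tutor_labels)
  motif <- tutor_motif(tutor, data.frame(onset_ms = c(0, 9, 16),
                                         offset_ms = c(6, 14, 23)))
  pupil <- label_track(c(rep(0, 7), tutor_labels, rep(4, 5), tutor_labels,
                         rep(0, 10)))
  sim <- build_similarity_matrix(tutor, pupil, tau = 1.5)
  m <- match_syllables(motif, section_pupil(pupil, motif$duration_ms), sim)
  # manual enumeration of the 4 defined neighbor comparisons
  on <- c(1L, 10L, 17L)   # first frame of each tutor syllable
  off <- c(6L, 14L, 23L)  # last frame of each tutor syllable
  p <- m$matches$global_start_frame
  len <- off - on + 1L
  comp <- c()
  for (s in 1:3) {
    if (s > 1) {
      rows <- on[s - 1]:(on[s] - 1L)
      cols <- (p[s] - length(rows)):(p[s] - 1L)
      comp <- c(comp, mean(sim$values[cbind(rows, cols)]))
    }
    if (s < 3) {
      rows <- (off[s] + 1L):off[s + 1]
      cols <- (p[s] + len[s]):(p[s] + len[s] + length(rows) - 1L)
      comp <- c(comp, mean(sim$values[cbind(rows, cols)]))
    }
  }
  expect_length(comp, 4L)
  expect_equal(as.numeric(sequence_score(motif, m$matches, sim)), mean(comp),
               tolerance = 1e-12)

  # single-syllable motif: sequence = 1 by convention, flagged
  m1 <- tutor_motif(label_track(rep(1, 8)),
                    data.frame(onset_ms = 0, offset_ms = 8))
  s1 <- sequence_score(m1, data.frame(global_start_frame = 1L),
                       build_similarity_matrix(m1$track, pupil, tau = 1.5))
  expect_equal(as.numeric(s1), 1)
  expect_true(attr(s1, "flagged"))
})

test_that("composite score is the exact product and is maximal for the tutor itself", {
  motif <- template_motif()
  self <- generate_song(n_bouts = 1, n_motifs = 2, seed = 41)
  r0 <- imitation_score(self$bouts, motif)
  expect_equal(r0$imitation_score, r0$acoustic_score * r0$sequence_score)
  expect_gt(r0$imitation_score, 0.99)

  set.seed(42)
  for (i in 1:8) {
    lev <- stats::runif(1, 0.2, 1.2)
    g <- generate_song(distortion = distortion_spec(lev), n_bouts = 1,
                       n_motifs = 2, seed = 500 + i)
    r <- imitation_score(g$bouts, motif)
    expect_equal(r$imitation_score, r$acoustic_score * r$sequence_score)
    expect_lt(r$imitation_score, r0$imitation_score)
  }
})

test_that("a silent pupil scores far below a real imitation", {
  motif <- template_motif()
  n <- as.integer(2.5 * motif$duration_ms * SR / 1000)
  silent_bout <- audio_clip(numeric(n), SR)
  r <- imitation_score(list(silent_bout), motif)
  expect_lt(r$acoustic_score, 0.2)
})

test_that("self-similarity is maximal for identical bout sets", {
  g <- generate_song(n_bouts = 2, n_motifs = 2,
                     distortion = distortion_spec(0, additive_noise_db = -50),
                     seed = 44)
  same <- self_similarity(g$bouts, g$bouts)
  degraded_bouts <- generate_song(
    distortion = distortion_spec(0, pitch_jitter_sd = 0.1,
                                 duration_jitter_sd = 0.1,
                                 additive_noise_db = -35),
    n_bouts = 2, n_motifs = 2, seed = 45)$bouts
  worse <- self_similarity(g$bouts, degraded_bouts)
  expect_gt(same$imitation_score, 0.85)
  expect_lt(worse$imitation_score, same$imitation_score)
  # normalization by the pre/pre score is exactly 1 for the pre/pre case
  expect_equal(same$imitation_score / same$imitation_score, 1.0)
})

test_that("imitation capacity reproduces the published worked example exactly", {
  scale <- capacity_scale()
  expect_equal(scale$dynamic_range, 0.093)
  cap <- imitation_capacity(0.116, scale)
  expect_equal(cap$capacity_fraction, (0.116 - 0.104) / 0.093)
  expect_equal(round(100 * cap$capacity_fraction, 1), 12.9)
  expect_equal(round(100 * cap$loss_fraction), 87)
  expect_equal(imitation_capacity(0.104, scale)$capacity_fraction, 0)
  expect_equal(imitation_capacity(0.197, scale)$capacity_fraction, 1)
  expect_false(cap$flagged)
  expect_true(imitation_capacity(0.09, scale)$flagged)
  expect_error(capacity_scale(0.1, 0.2), class = "songeval_validation_error")
})

test_that("imitation capacity is invariant under consistent affine rescaling", {
  set.seed(47)
  for (i in 1:10) {
    a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, -0.2, 0.2)
    s <- stats::runif(1, 0.05, 0.3)
    c1 <- imitation_capacity(s, capacity_scale(0.197, 0.104))
    c2 <- imitation_capacity(a * s + b,
                             capacity_scale(a * 0.197 + b, a * 0.104 + b))
    expect_equal(c1$capacity_fraction, c2$capacity_fraction,
                 tolerance = 1e-10)
  }
})
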