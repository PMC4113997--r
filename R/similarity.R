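# Tutor-imitation scoring.
#
# Pupil song is compared with the tutor motif in acoustic-feature space:
# a frame-by-frame similarity matrix exp(-d/tau) on z-scored features, a
# best-placement search of each tutor syllable within overlapping pupil
# sections (each twice the motif duration), a sequence score from the
# acoustic match of the segments flanking each placed syllable, and the
# composite imitation score = acoustic x sequence.

similarity_features <- c("fm", "wiener_entropy", "pitch_goodness", "pitch")

feature_matrix <- function(track, features = similarity_features) {
  do.call(cbind, lapply(features, function(f) track[[f]]))
}

#' Tutor motif container
#'
#' @param track a `feature_track` of the motif.
#' @param syllables data.frame with `onset_ms`, `offset_ms` (half-open,
#'   time-ordered, non-overlapping, within the track).
#' @return a `tutor_motif` object.
#' @export
tutor_motif <- function(track, syllables) {
  assert_that(inherits(track, "feature_track"), "track must be a feature_track")
  assert_that(is.data.frame(syllables) && nrow(syllables) >= 1 &&
                all(c("onset_ms", "offset_ms") %in% names(syllables)),
              "syllables must be a data.frame with onset_ms/offset_ms and >= 1 row")
  assert_that(all(syllables$offset_ms > syllables$onset_ms),
              "syllable offsets must exceed onsets")
  if (nrow(syllables) > 1) {
    assert_that(all(diff(syllables$onset_ms) > 0) &&
                  all(syllables$onset_ms[-1] >= syllables$offset_ms[-nrow(syllables)]),
                "syllables must be time-ordered and non-overlapping")
  }
  dur <- max(track$frame_times) + track$params$step_ms
  assert_that(all(syllables$offset_ms <= dur + track$params$window_ms),
              "syllables must lie within the motif track")
  structure(list(track = track, syllables = syllables, duration_ms = dur),
            class = "tutor_motif")
}

# Frame-index range [first, last] whose centers fall in [onset, offset).
syllable_frame_range <- function(track, onset_ms, offset_ms) {
  idx <- which(track$frame_times >= onset_ms & track$frame_times < offset_ms)
  assert_that(length(idx) >= 1, "syllable spans no frames")
  c(idx[1], idx[length(idx)])
}

#' Frame-to-frame similarity matrix between two feature tracks
#'
#' Features are z-scored with the tutor track's statistics (so distance is
#' unit-free and fixed per tutor); entry (i, j) = exp(-d(i, j)/tau) with d
#' the Euclidean distance between normalized feature vectors.  By default
#' tau is the median pairwise distance among the tutor's non-silent frames,
#' making the similarity scale a property of the reference song.
#'
#' @param tutor,pupil `feature_track`s.
#' @param features character vector of feature names used.
#' @param tau distance scale; `NULL` for the tutor-median default.
#' @return a `similarity_matrix`: `values` (tutor frames x pupil frames, in
#'   \[0, 1\]), `frame_step_ms`, `tau`, and the silence flags of both tracks.
#' @export
build_similarity_matrix <- function(tutor, pupil,
                                    features = similarity_features,
                                    tau = NULL) {
  assert_that(inherits(tutor, "feature_track") &&
                inherits(pupil, "feature_track"),
              "tutor and pupil must be feature_tracks")
  assert_that(all(features %in% names(tutor)) && all(features %in% names(pupil)),
              "mismatched feature sets")
  assert_that(tutor$params$step_ms == pupil$params$step_ms,
              "tracks must share a frame step")
  a <- feature_matrix(tutor, features)
  b <- feature_matrix(pupil, features)
  ref <- if (any(!tutor$silent)) a[!tutor$silent, , drop = FALSE] else a
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  az <- sweep(sweep(a, 2, mu), 2, sdv, `/`)
  bz <- sweep(sweep(b, 2, mu), 2, sdv, `/`)
  if (is.null(tau)) tau <- median_pairwise_distance(az[!tutor$silent, , drop = FALSE])
  assert_that(is.numeric(tau) && tau > 0, "tau must be positive")
  d2 <- outer(rowSums(az^2), rowSums(bz^2), `+`) - 2 * tcrossprod(az, bz)
  d2[d2 < 0] <- 0
  structure(list(values = exp(-sqrt(d2) / tau),
                 frame_step_ms = tutor$params$step_ms, tau = tau,
                 tutor_silent = tutor$silent, pupil_silent = pupil$silent),
            class = "similarity_matrix")
}

median_pairwise_distance <- function(z) {
  n <- nrow(z)
  assert_that(n >= 2, "need >= 2 non-silent reference frames for tau")
  if (n > 600) z <- z[round(seq(1, n, length.out = 600)), , drop = FALSE]
  stats::median(stats::dist(z))
}

#' Cut a pupil bout into overlapping scoring sections
#'
#' Sections are exactly twice the tutor-motif duration and advance by
#' `stride_ms` (default: one motif duration, i.e. 50% overlap); the last
#' section is right-aligned to the bout end so no tail is lost.
#'
#' @param pupil a `feature_track`.
#' @param tutor_duration_ms motif duration in ms.
#' @param stride_ms section stride; `NULL` for one motif duration.
#' @return data.frame with `start_frame`, `end_frame` (1-based, inclusive).
#' @export
section_pupil <- function(pupil, tutor_duration_ms, stride_ms = NULL) {
  step <- pupil$params$step_ms
  np <- n_frames(pupil)
  len <- as.integer(round(2 * tutor_duration_ms / step))
  if (np < len) {
    stop_songeval(sprintf(
      "pupil bout (%d frames) shorter than twice the tutor motif (%d frames)",
      np, len), "songeval_short_bout_error")
  }
  stride <- as.integer(round((stride_ms %||% tutor_duration_ms) / step))
  assert_that(stride >= 1, "stride too small for frame step")
  starts <- seq.int(1L, np - len + 1L, by = stride)
  if (starts[length(starts)] != np - len + 1L) {
    starts <- c(starts, np - len + 1L)   # right-aligned boundary section
  }
  data.frame(start_frame = starts, end_frame = starts + len - 1L)
}

# Mean similarity along the diagonal starting at (rows[1], p), with
# silence-flagged pupil frames excluded when they cover < half the span;
# placements falling mostly on silence are scored over all frames so they
# cannot win by cherry-picking a few loud frames.
diag_scores <- function(sim, row_first, row_last, min_valid_frac = 0.5) {
  v <- sim$values
  len <- row_last - row_first + 1L
  np <- ncol(v)
  npos <- np - len + 1L
  if (npos < 1L) return(numeric(0))
  ok <- as.numeric(!sim$pupil_silent)
  acc <- numeric(npos); accv <- numeric(npos); cnt <- numeric(npos)
  for (k in seq_len(len)) {
    cols <- k:(k + npos - 1L)
    row <- v[row_first + k - 1L, cols]
    acc <- acc + row
    accv <- accv + row * ok[cols]
    cnt <- cnt + ok[cols]
  }
  ifelse(cnt >= min_valid_frac * len, accv / pmax(cnt, 1), acc / len)
}

#' Place each tutor syllable in the pupil sections
#'
#' For every tutor syllable, searches all sections and within-section offsets
#' for the placement maximizing the mean similarity along the aligned
#' diagonal; ties go to the earliest section, then the earliest offset.  The
#' acoustic score is the duration-weighted mean of per-syllable best
#' similarities.
#'
#' @param motif a [tutor_motif].
#' @param sections data.frame from [section_pupil()].
#' @param sim a `similarity_matrix` between `motif$track` and the pupil.
#' @return list with `acoustic_score` and `matches` (data.frame: syllable
#'   index, section index, offset within section in ms, global start frame,
#'   similarity).
#' @export
match_syllables <- function(motif, sections, sim) {
  assert_that(nrow(sections) >= 1, "need >= 1 pupil section")
  step <- sim$frame_step_ms
  syl <- motif$syllables
  n_syl <- nrow(syl)
  best <- data.frame(tutor_syllable_index = seq_len(n_syl),
                     pupil_section_index = NA_integer_,
                     pupil_offset_ms = NA_real_,
                     global_start_frame = NA_integer_,
                     acoustic_similarity = NA_real_)
  for (s in seq_len(n_syl)) {
    fr <- syllable_frame_range(motif$track, syl$onset_ms[s], syl$offset_ms[s])
    len <- fr[2] - fr[1] + 1L
    scores <- diag_scores(sim, fr[1], fr[2])
    best_val <- -Inf
    for (sec in seq_len(nrow(sections))) {
      p_lo <- sections$start_frame[sec]
      p_hi <- min(sections$end_frame[sec] - len + 1L, length(scores))
      if (p_hi < p_lo) next
      local <- scores[p_lo:p_hi]
      i <- which.max(local)            # first max: earliest offset
      if (local[i] > best_val) {       # strict: earliest section wins ties
        best_val <- local[i]
        best$pupil_section_index[s] <- sec
        best$pupil_offset_ms[s] <- (i - 1L) * step
        best$global_start_frame[s] <- p_lo + i - 1L
        best$acoustic_similarity[s] <- local[i]
      }
    }
    assert_that(is.finite(best_val), "no admissible placement for a syllable")
  }
  w <- syl$offset_ms - syl$onset_ms
  list(acoustic_score = stats::weighted.mean(best$acoustic_similarity, w),
       matches = best)
}

#' Sequence score from flanking-segment similarity
#'
#' For each placed tutor syllable, compares the tutor segment spanning from
#' the previous syllable's onset up to this syllable's onset (and likewise
#' the segment up to the next syllable's offset) against the pupil stretch
#' immediately flanking the placement, and averages the mean diagonal
#' similarities over all defined neighbor comparisons.  A single-syllable
#' motif has no neighbors and scores 1 by convention (flagged).
#'
#' @param motif a [tutor_motif].
#' @param matches data.frame from [match_syllables()].
#' @param sim the same `similarity_matrix`.
#' @return sequence similarity in \[0, 1\]; attribute `flagged` is TRUE for
#'   the single-syllable convention.
#' @export
sequence_score <- function(motif, matches, sim) {
  syl <- motif$syllables
  n_syl <- nrow(syl)
  if (n_syl == 1) return(structure(1, flagged = TRUE))
  track <- motif$track
  np <- ncol(sim$values)
  ranges <- lapply(seq_len(n_syl), function(s)
    syllable_frame_range(track, syl$onset_ms[s], syl$offset_ms[s]))
  comps <- numeric(0)
  for (s in seq_len(n_syl)) {
    p <- matches$global_start_frame[s]
    len_s <- ranges[[s]][2] - ranges[[s]][1] + 1L
    if (s > 1) {  # preceding: previous syllable plus the gap
      r1 <- ranges[[s - 1]][1]
      r2 <- ranges[[s]][1] - 1L
      w <- r2 - r1 + 1L
      q <- p - w
      if (q >= 1) comps <- c(comps, diag_block_mean(sim, r1, r2, q))
    }
    if (s < n_syl) {  # following: the gap plus the next syllable
      r1 <- ranges[[s]][2] + 1L
      r2 <- ranges[[s + 1]][2]
      w <- r2 - r1 + 1L
      q <- p + len_s
      if (q + w - 1L <= np) comps <- c(comps, diag_block_mean(sim, r1, r2, q))
    }
  }
  if (length(comps) == 0) return(structure(1, flagged = TRUE))
  structure(mean(comps), flagged = FALSE)
}

# Mean along one specific diagonal placement (tutor rows r1:r2 against pupil
# columns starting at q), with the same silence-exclusion rule as placement.
diag_block_mean <- function(sim, r1, r2, q, min_valid_frac = 0.5) {
  len <- r2 - r1 + 1L
  rows <- r1:r2
  cols <- q:(q + len - 1L)
  vals <- sim$values[cbind(rows, cols)]
  ok <- !sim$pupil_silent[cols]
  if (sum(ok) >= min_valid_frac * len) mean(vals[ok]) else mean(vals)
}

#' Composite tutor-imitation score over pupil bouts
#'
#' Scores each pupil bout against the tutor motif (acoustic placement +
#' sequence), averages acoustic and sequence scores over bouts (unweighted),
#' and returns the composite imitation score = acoustic x sequence.
#'
#' @param pupil_bouts list of `feature_track`s or [audio_clip]s.
#' @param motif a [tutor_motif].
#' @param stride_ms section stride passed to [section_pupil()].
#' @param tau similarity scale; `NULL` for the tutor-median default (computed
#'   once and shared across bouts).
#' @param features feature names used for similarity.
#' @return an `imitation_result`: `acoustic_score`, `sequence_score`,
#'   `imitation_score` (= product), `matches` (per bout), `n_bouts`.
#' @export
imitation_score <- function(pupil_bouts, motif, stride_ms = NULL, tau = NULL,
                            features = similarity_features) {
  assert_that(is.list(pupil_bouts) && length(pupil_bouts) >= 1,
              "need >= 1 pupil bout")
  tracks <- lapply(pupil_bouts, function(b)
    if (inherits(b, "feature_track")) b else extract_features(b))
  if (is.null(tau)) {
    a <- feature_matrix(motif$track, features)
    ref <- if (any(!motif$track$silent)) a[!motif$track$silent, , drop = FALSE]
           else a
    mu <- colMeans(ref); sdv <- apply(ref, 2, stats::sd); sdv[sdv < 1e-12] <- 1
    az <- sweep(sweep(ref, 2, mu), 2, sdv, `/`)
    tau <- median_pairwise_distance(az)
  }
  aco <- numeric(0); seqs <- numeric(0); all_matches <- list()
  for (i in seq_along(tracks)) {
    res <- tryCatch({
      sim <- build_similarity_matrix(motif$track, tracks[[i]],
                                     features = features, tau = tau)
      sections <- section_pupil(tracks[[i]], motif$duration_ms, stride_ms)
      m <- match_syllables(motif, sections, sim)
      sq <- sequence_score(motif, m$matches, sim)
      list(a = m$acoustic_score, s = as.numeric(sq), matches = m$matches)
    }, songeval_short_bout_error = function(e) {
      warning(sprintf("bout %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      aco <- c(aco, res$a); seqs <- c(seqs, res$s)
      all_matches[[length(all_matches) + 1L]] <- res$matches
    }
  }
  assert_that(length(aco) >= 1, "no valid pupil bouts (all too short)")
  structure(list(acoustic_score = mean(aco), sequence_score = mean(seqs),
                 imitation_score = mean(aco) * mean(seqs),
                 matches = all_matches, n_bouts = length(aco)),
            class = "imitation_result")
}

#' @export
print.imitation_result <- function(x, ...) {
  cat(sprintf(paste0("<imitation_result> acoustic %.3f x sequence %.3f = ",
                     "imitation %.3f (%d bouts)\n"),
              x$acoustic_score, x$sequence_score, x$imitation_score, x$n_bouts))
  invisible(x)
}

#' Self-similarity between two sets of a bird's own bouts
#'
#' Runs the imitation-scoring algorithm with a motif extracted from
#' `bouts_a` as the reference and `bouts_b` as pupil.  The motif is the
#' first run of amplitude-segmented syllables in the first bout whose
#' inter-syllable gaps stay below `motif_gap_ms` (one motif rendition; the
#' longer inter-motif silence ends the run).  Used to track song
#' degradation over time; usage is conventionally symmetric but not
#' enforced.
#'
#' @param bouts_a,bouts_b lists of `feature_track`s or [audio_clip]s.
#' @param motif optional explicit [tutor_motif]; extracted from `bouts_a`
#'   when `NULL`.
#' @param motif_gap_ms gaps at or above this end the motif run (ms).
#' @param ... passed to [imitation_score()].
#' @return an `imitation_result`.
#' @export
self_similarity <- function(bouts_a, bouts_b, motif = NULL,
                            motif_gap_ms = 55, ...) {
  assert_that(length(bouts_a) >= 1 && length(bouts_b) >= 1,
              "both bout sets must be non-empty")
  if (is.null(motif)) {
    ref <- bouts_a[[1]]
    ref_track <- if (inherits(ref, "feature_track")) ref else
      extract_features(ref)
    segs <- segment_syllables(ref_track)
    assert_that(nrow(segs) >= 1, "no syllables found in reference bout")
    k <- nrow(segs)
    if (k > 1) {
      gaps <- segs$onset_ms[-1] - segs$offset_ms[-k]
      brk <- which(gaps >= motif_gap_ms)
      if (length(brk)) k <- brk[1]
    }
    segs <- segs[seq_len(k), , drop = FALSE]
    motif <- tutor_motif(
      subtrack(ref_track, segs$onset_ms[1], segs$offset_ms[k]),
      data.frame(onset_ms = segs$onset_ms - segs$onset_ms[1],
                 offset_ms = segs$offset_ms - segs$onset_ms[1]))
  }
  imitation_score(bouts_b, motif, ...)
}

#' Extract a time window of a feature track
#'
#' @param track a `feature_track`.
#' @param from_ms,to_ms half-open window `[from, to)` in ms.
#' @return a `feature_track` with times rebased to the window start.
#' @export
subtrack <- function(track, from_ms, to_ms) {
  keep <- track$frame_times >= from_ms & track$frame_times < to_ms
  assert_that(any(keep), "window contains no frames")
  out <- track
  for (f in c("frame_times", "amplitude", "fm", "wiener_entropy",
              "pitch_goodness", "pitch", "silent")) {
    out[[f]] <- track[[f]][keep]
  }
  out$frame_times <- out$frame_times - out$frame_times[1]
  out
}

#' Imitation-capacity scale
#'
#' The linear scale on which raw imitation scores are expressed as a
#' fraction of the dynamic range between the average control-bird score and
#' the average pairwise score of unrelated adult birds.
#'
#' @param control_mean average imitation score of intact tutored birds
#'   (default 0.197).
#' @param unrelated_mean average pairwise similarity among unrelated adults
#'   (default 0.104).
#' @return a `capacity_scale` with `control_mean`, `unrelated_mean`,
#'   `dynamic_range`.
#' @export
capacity_scale <- function(control_mean = 0.197, unrelated_mean = 0.104) {
  assert_that(control_mean > unrelated_mean,
              "control_mean must exceed unrelated_mean (dynamic range > 0)")
  structure(list(control_mean = control_mean, unrelated_mean = unrelated_mean,
                 dynamic_range = control_mean - unrelated_mean),
            class = "capacity_scale")
}

#' Rescale an imitation score to imitation capacity
#'
#' capacity = (score - unrelated_mean) / dynamic_range; loss = 1 - capacity.
#' Values outside \[0, 1\] are returned unclipped with `flagged = TRUE`.
#'
#' @param score raw imitation score (or an `imitation_result`).
#' @param scale a [capacity_scale].
#' @return list with `capacity_fraction`, `loss_fraction`, `flagged`.
#' @export
imitation_capacity <- function(score, scale = capacity_scale()) {
  if (inherits(score, "imitation_result")) score <- score$imitation_score
  assert_that(inherits(scale, "capacity_scale"), "scale must be a capacity_scale")
  assert_that(scale$dynamic_range > 0, "dynamic_range must be positive")
  capacity <- (score - scale$unrelated_mean) / scale$dynamic_range
  list(capacity_fraction = capacity, loss_fraction = 1 - capacity,
       flagged = capacity < 0 || capacity > 1)
}
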