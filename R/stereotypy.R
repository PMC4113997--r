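# Syllable stereotypy and bout maturity from spectrogram cross-correlation.
#
# Two spectrograms are compared by correlating their band-restricted power
# columns slice-by-slice, summing the correlation matrix along diagonals
# (normalized by overlap) to get a lag-correlation function, and taking its
# maximum.

#' Peak lag correlation between two spectrograms
#'
#' Computes the Pearson correlation of band-restricted power spectra between
#' every 1 ms slice pair, forms the lag-correlation function as the
#' overlap-normalized mean along each diagonal (lags with fewer than
#' `min_overlap_frac` of the shorter input's slices overlapping are
#' dropped, to avoid edge spikes), and returns its maximum.  Zero-variance
#' (silent) slices are excluded from the diagonal means.
#'
#' @param a,b `spectrogram_mt` objects on identical frequency grids.
#' @param band_hz analysis band (closed, on bin centers).
#' @param min_overlap_frac minimum valid overlap per admissible lag, as a
#'   fraction of the shorter spectrogram.
#' @return the peak correlation (scalar); attributes `lag_ms` (lag at the
#'   peak, b relative to a) and `lag_function` (data.frame lag_ms/correlation).
#' @export
spectrogram_similarity <- function(a, b, band_hz = default_band,
                                   min_overlap_frac = 0.5) {
  assert_that(inherits(a, "spectrogram_mt") && inherits(b, "spectrogram_mt"),
              "inputs must be spectrogram_mt objects")
  assert_that(length(a$freqs) == length(b$freqs) &&
                all(abs(a$freqs - b$freqs) < 1e-9),
              "frequency grids do not match")
  assert_that(a$params$step_ms == b$params$step_ms,
              "frame steps do not match")
  bins <- band_bins(a$freqs, band_hz)
  assert_that(length(bins) >= 3, "band contains too few bins")
  pa <- a$power[bins, , drop = FALSE]
  pb <- b$power[bins, , drop = FALSE]
  za <- standardize_cols(pa)
  zb <- standardize_cols(pb)
  cmat <- crossprod(za$z, zb$z) / (length(bins) - 1)   # na x nb correlations
  na <- ncol(pa); nb <- ncol(pb)
  valid <- outer(za$valid, zb$valid, `&`)
  lag_of <- outer(seq_len(na), seq_len(nb), function(i, j) j - i)
  off <- na  # shift lags to positive indices
  keep <- as.vector(valid)
  sums <- tabulate_weighted(as.vector(lag_of)[keep] + off,
                            as.vector(cmat)[keep], nb + na - 1)
  counts <- tabulate(as.vector(lag_of)[keep] + off, nb + na - 1)
  min_n <- min_overlap_frac * min(na, nb)
  ok <- counts >= pmax(min_n, 1)
  assert_that(any(ok), "no lag has sufficient valid overlap")
  lags <- (seq_len(nb + na - 1) - off) * a$params$step_ms
  corr <- sums[ok] / counts[ok]
  i <- which.max(corr)
  structure(corr[i], lag_ms = lags[ok][i],
            lag_function = data.frame(lag_ms = lags[ok], correlation = corr))
}

standardize_cols <- function(p) {
  mu <- colMeans(p)
  ctr <- sweep(p, 2, mu)
  ss <- sqrt(colSums(ctr^2) / (nrow(p) - 1))
  valid <- ss > 1e-300
  ss[!valid] <- 1
  list(z = sweep(ctr, 2, ss, `/`), valid = valid)
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

as_spectrogram <- function(x, ...) {
  if (inherits(x, "spectrogram_mt")) x else compute_multitaper_spectrogram(x, ...)
}

#' Syllable stereotypy of a syllable database
#'
#' Randomly selects `n_select` syllables without replacement; for each,
#' draws `n_sample` comparison syllables (with replacement, excluding the
#' selected syllable itself by default), computes the peak spectrogram lag
#' correlation against each, and takes the 95th percentile of that
#' distribution.  The stereotypy statistic is the mean of the per-selected
#' 95th percentiles.
#'
#' @param db list of [audio_clip]s or `spectrogram_mt`s (>= `n_select`).
#' @param n_select number of probe syllables.
#' @param n_sample comparisons per probe.
#' @param seed RNG seed for reproducible sampling.
#' @param exclude_self drop the probe itself from its comparison pool.
#' @param percentile_method `"linear"` (interpolated, default) or
#'   `"nearest_rank"`.
#' @param band_hz analysis band.
#' @return a `stereotypy_result`: `per_selected_p95`, `stereotypy` (their
#'   mean), `selected` (indices), `n_selected`, `n_sampled_per_selected`.
#' @export
syllable_stereotypy <- function(db, n_select = 100, n_sample = 100,
                                seed = NULL, exclude_self = TRUE,
                                percentile_method = c("linear", "nearest_rank"),
                                band_hz = default_band) {
  percentile_method <- match.arg(percentile_method)
  n <- length(db)
  assert_that(n >= 2 && n >= n_select,
              sprintf("database (%d) smaller than n_select (%d)", n, n_select))
  specs <- lapply(db, as_spectrogram)
  with_seed(seed, {
    selected <- sample.int(n, n_select, replace = FALSE)
    p95 <- vapply(selected, function(i) {
      pool <- if (exclude_self) setdiff(seq_len(n), i) else seq_len(n)
      draw <- sample(pool, n_sample, replace = TRUE)
      sims <- vapply(draw, function(j)
        as.numeric(spectrogram_similarity(specs[[i]], specs[[j]],
                                          band_hz = band_hz)), numeric(1))
      percentile(sims, 0.95, percentile_method)
    }, numeric(1))
    structure(list(per_selected_p95 = p95, stereotypy = mean(p95),
                   selected = selected, n_selected = n_select,
                   n_sampled_per_selected = n_sample),
              class = "stereotypy_result")
  })
}

#' @export
print.stereotypy_result <- function(x, ...) {
  cat(sprintf("<stereotypy_result> stereotypy %.3f (%d probes x %d samples)\n",
              x$stereotypy, x$n_selected, x$n_sampled_per_selected))
  invisible(x)
}

#' Bout maturity index
#'
#' The mean, over all pairs of bouts, of the peak spectrogram
#' cross-correlation between whole bouts: high when successive renditions
#' are near-identical (crystallized song), low for variable juvenile song.
#'
#' @param bouts list (>= 2) of [audio_clip]s or `spectrogram_mt`s.
#' @param band_hz analysis band.
#' @return the maturity index (scalar).
#' @export
maturity_index <- function(bouts, band_hz = default_band) {
  assert_that(length(bouts) >= 2, "need >= 2 bouts for a maturity index")
  specs <- lapply(bouts, as_spectrogram)
  pairs <- utils::combn(length(specs), 2)
  mean(apply(pairs, 2, function(ij)
    as.numeric(spectrogram_similarity(specs[[ij[1]]], specs[[ij[2]]],
                                      band_hz = band_hz))))
}
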