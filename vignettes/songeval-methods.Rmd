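---
title: "songeval: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{songeval: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind its three
pipelines — tutor-imitation scoring, song stereotypy, and event-aligned
spike-train statistics — together with the conventions and design decisions
a maintainer or reviewer would want spelled out. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Acoustic features

All song analysis rests on a multitaper spectrogram: k = 2 DPSS (Slepian)
tapers with time–bandwidth product 1.5, a 10 ms analysis window and a 1 ms
step, at a default sample rate of 40 kHz. The tapers are computed from the
classic symmetric tridiagonal formulation (its eigenvectors coincide with
the Slepian sequences), made unit-energy, and the per-taper eigenspectra
are averaged. Frame timestamps are window centers; all intervals in the
package are half-open `[onset, offset)` and all times are in ms.

Per frame, inside a fixed 860 Hz–8.6 kHz analysis band (one band across
every module, so similarity and stereotypy see the same spectral support):

* **amplitude** — `10 log10` of summed band power;
* **Wiener entropy** — `log(geometric mean / arithmetic mean)` of band
  power. It is ≤ 0 by Jensen's inequality (≈ 0 for white noise, strongly
  negative for tones), and the implementation clamps tiny positive
  numerical residue;
* **pitch goodness** and **pitch** — height and location of the cepstral
  peak (real cepstrum of the two-sided log power spectrum), searched over
  quefrencies corresponding to 350–4000 Hz. For harmonic stacks the peak
  sits at the fundamental's quefrency;
* **FM** — `atan2` of the RMS temporal derivative to the RMS spectral
  derivative of band log-power, in degrees: 0° for a steady tone, large
  for fast sweeps.

**Silence convention.** A frame is flagged silent when its band power is
essentially zero (below an absolute floor of `1e-12` per-bin-scale power)
*or* when its amplitude falls more than 45 dB below the clip's loudest
frame. The second, relative criterion matters: recordings and synthetic
bouts have low-level background noise in the gaps, and treating those
frames as "sound" would hand them meaningless pitch and entropy values
that contaminate similarity scores. Silent frames get entropy 0, pitch
goodness 0, pitch 0 Hz, and are excluded from feature histograms and from
similarity diagonals (below). The floor value itself is a numerical guard,
not a tuning parameter.

**Syllable segmentation** is amplitude gating: maximal runs of frames at or
above a threshold, gaps shorter than 5 ms bridged, runs shorter than 10 ms
discarded. The threshold default is the clip's noise floor (10th
amplitude percentile) + 12 dB; all three knobs are exposed because no
universal values exist. Reported boundaries are frame centers, so a
detected onset can sit up to about half an analysis window away from the
waveform-level onset depending on the threshold; the cross-module tests
use a gate a fixed distance below the syllable plateau, where the detected
and true boundaries agree to ±2 frames.

## Imitation scoring

Similarity between tutor frame *i* and pupil frame *j* is
`exp(−d(i,j)/τ)` with `d` the Euclidean distance between feature vectors
(FM, Wiener entropy, pitch goodness, pitch — amplitude is deliberately
excluded so loudness differences between recordings don't masquerade as
imitation quality). Design decisions:

* **Normalization.** Features are z-scored with the *tutor's* non-silent
  frame statistics. Using the tutor as the reference makes the distance
  unit-free and, importantly, identical across all pupils of one tutor, so
  scores are comparable within a tutor's brood.
* **Distance scale τ.** Default: the median pairwise distance among the
  tutor's non-silent frames. This is data-driven, keeps `exp(−d/τ)` spread
  over (0, 1) rather than saturating, and again is a property of the
  reference song, not of the pupil being scored. Config-exposed.
* **Sectioning.** Pupil bouts are cut into sections of exactly twice the
  tutor-motif duration, advancing by one motif duration (50% overlap),
  with the last section right-aligned to the bout end. The overlap
  guarantees every motif-length stretch of the pupil lies wholly inside
  some section, so no placement is lost at section boundaries.
* **Placement.** Each tutor syllable is scored at every admissible
  (section, offset) as the mean similarity along the aligned diagonal;
  the best placement wins, ties going to the earliest section then the
  earliest offset (determinism). The acoustic score is the
  duration-weighted mean of per-syllable best similarities — longer
  syllables carry proportionally more of the song, which an unweighted
  mean would misrepresent.
* **Silence exclusion.** Silence-flagged pupil frames are excluded from
  diagonal means, *unless* they cover half or more of the span, in which
  case the plain mean over all frames is used. The exception prevents a
  mostly-silent placement from winning on a handful of loud frames.
* **Sequence score.** For each placed syllable, the tutor segment from the
  previous syllable's onset up to this syllable's onset (previous syllable
  plus its gap) is compared against the pupil stretch immediately
  preceding the placement, and symmetrically for the following segment;
  the sequence score is the mean over all defined flanking comparisons.
  This is what makes the composite score sensitive to syllable *order*:
  a pupil singing all syllables perfectly but in reverse keeps an acoustic
  score of 1 while the flanking comparisons collapse. A single-syllable
  motif has no neighbors and scores 1 by convention, flagged.
* **Aggregation.** Acoustic and sequence scores are unweighted means over
  bouts; the imitation score is the product of the two means, exactly.

**Imitation capacity** is the affine rescaling
`(score − unrelated_mean)/(control_mean − unrelated_mean)` with defaults
0.197 (control) and 0.104 (unrelated), dynamic range 0.093; loss is its
complement. Values outside [0, 1] are returned unclipped with a flag —
clipping would hide calibration problems. Note the published scale
calibrates scores produced by the original feature implementation on real
song; synthetic toy songs land on a different effective scale, so capacity
numbers for generator output are illustrative only (and get flagged when
out of range).

**Self-similarity** reuses the identical algorithm with the bird's own
earlier song as reference. The reference motif is the first run of
segmented syllables whose inter-syllable gaps stay below 55 ms; the first
gap at or above that ends the motif, separating the short intra-motif gaps
from the longer inter-motif pause.

## Stereotypy and maturity

Two spectrograms are compared by the peak of the lag-correlation function:
Pearson correlation between band-restricted power columns for every slice
pair, diagonal sums normalized by the number of overlapping slices per lag
(an unnormalized sum would trivially favor lag 0), lags with less than
half the shorter input overlapping dropped (edge spikes from one or two
slices), zero-variance (silent) slices excluded. The statistic is
symmetric up to lag sign and invariant to uniform power scaling.

Syllable stereotypy selects `n_select` probes without replacement; each
probe is compared against `n_sample` syllables drawn *with* replacement
from the database excluding the probe itself (self-comparisons are
trivially 1 and would inflate the statistic; a config flag restores
inclusion). The per-probe summary is the 95th percentile of the
similarity distribution, computed by linear interpolation between closest
ranks (deterministic across sample sizes; a nearest-rank option exists),
and the stereotypy statistic is the mean over probes. The maturity index
applies the same peak lag-correlation to whole bouts, averaged over all
bout pairs.

## Neural response statistics

PSTHs count spikes in half-open event-relative bins, excluding events
whose windows are truncated by the recording edges, and convert to Hz by
`n_events × bin width`.

* **Window test**: paired two-sided t-test of 150 ms post- vs pre-onset
  counts per event. If every difference is zero the t statistic is
  undefined; p = 1 is returned with a flag rather than NaN.
* **Circular-shift bootstrap**: over a 2 s window around each event,
  each event's spikes are shifted together by an independent uniform
  ±1 s draw and wrapped within the window; the PSTH peak (10 ms bins by
  default — fine enough for fast responses, coarse enough to avoid
  empty-bin noise; config-exposed) within the post-onset second is
  compared with the null peak distribution over 1000 such surrogates.
  `bootstrap_p` is the plain exceedance fraction. Because the peak is a
  small integer count, ties with the null are common and the strict
  "exceeds the 95th percentile" rule is structurally conservative; the
  significance flag therefore uses the **mid-p** convention (strictly
  above plus half the ties) against α = 0.05, the standard tie correction
  for discrete exceedance tests. `use_mid_p = FALSE` restores the strict
  percentile rule, and α is configurable (0.02 appears in the literature
  as a stricter reported cut).
* **Averaged response**: each unit's event-averaged rate vector is
  circularly rotated by an independent uniform draw before averaging
  across units; null distributions of the population peak rate and of the
  maximal 150 ms windowed count are collected over the whole window,
  while the real statistics are taken within 150 ms of onset. The
  reported p is the larger of the two exceedance probabilities — a
  deliberately conservative "both tests must agree" summary.
* **Latency/duration**: 2 ms bins; each post-onset bin count is z-tested
  against the mean and SD of the pooled pre-stimulus (1 s) bin counts,
  with a 0.5-count continuity correction for low counts. Latency is the
  left edge of the first bin opening a run of 5 consecutive significant
  bins (p < 0.05); the response closes at the first later bin opening a
  run of 10 consecutive non-significant bins, and duration is the
  distance between those edges. Either is NA, flagged, if no qualifying
  run exists; a zero-variance baseline is an error since z is undefined.
  Because single noise bins can restart the closing run, recovered
  durations occasionally overshoot by a few bins — visible in the
  acceptance recovery rates.
* **Motif-locked modulation**: motifs are truncated to the shortest
  motif's whole-bin duration; surrogates shift each motif's spikes
  circularly within that motif's own span, which preserves per-motif
  counts and ISI structure while destroying phase locking.
* **Antidromic significance**: band power (200 Hz–2 kHz) of the
  trial-averaged trace in the 2–17 ms post-stimulus window, from a
  rectangular-window periodogram of that 15 ms segment, tested one-sided
  (Welch) against no-response sites. When each group is a list of trial
  sets, every site contributes one band power. When a single trial set is
  supplied per group, its trials are partitioned into 8 disjoint
  contiguous sub-averages so the t-test has replicates; sub-averaging
  (rather than per-trial spectra) keeps the statistic faithful to the
  averaged-response definition while providing within-group variance.
  Note that a 15 ms rectangular window leaks low-frequency energy
  broadly, so a strong below-band drift is not perfectly invisible to the
  band statistic; the tests treat mains-like drift as common-mode across
  sites, which is how it occurs on a rig.

All surrogate procedures take a `seed` and are bit-reproducible; seeding
is implemented with save/restore of the RNG state so package internals
never perturb the caller's random stream.

## Synthetic generators

The song generator emulates the structure the analyses care about:
harmonic-stack syllables (fundamental + 1/h rolloff harmonics, optional
linear FM sweep, 5 ms raised-cosine edges) separated by silent gaps,
repeated as motifs within a bout (default 3 syllables of 85/60/110 ms at
620/980/1420 Hz, gaps 35/45 ms, 3 motif renditions, 120 ms inter-motif
pause — the clear separation between intra-motif gaps and the inter-motif
pause mirrors real zebra finch song, where bouts pause much longer between
motifs than between syllables). It does **not** attempt zebra finch
timbre, syringeal biomechanics, or the correlated rendition-to-rendition
variability of real song; passing tests on generated song demonstrate the
*algorithms*' behavior under known ground truth, not field performance on
recordings.

A scalar distortion `level` maps onto continuous knobs — per-rendition
fractional pitch jitter SD `0.08·level`, duration jitter SD `0.12·level`,
additive white noise at `−55 + 30·level` dB re the syllable reference
amplitude (none at level 0) — so level 0 is a sample-exact copy and the
expected score declines smoothly with level. Discrete corruptions
(syllable drops, sequence shuffles) exist as explicit knobs but are not
part of the level mapping, because their all-or-nothing nature makes
per-seed monotonicity checks noisy.

Spike trains are inhomogeneous Poisson: a constant baseline plus a
rectangular rate increment of stated latency, amplitude and duration after
each event (negative amplitudes thin the baseline). The rectangular shape
is a deliberate choice over an alpha function: it makes latency and
duration ground truth unambiguous for recovery tests. Antidromic trials
are Gaussian noise traces with an optional damped post-stimulus sinusoid.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in a couple of minutes while keeping Monte-Carlo
error well inside the asserted tolerances: 500 Poisson units at 200
shuffles for bootstrap calibration (the exact binomial 99% band around
0.05 is the acceptance region), 20 seeds for latency/duration recovery
and for the 4-level distortion monotonicity (2 bouts × 2 motifs per
condition), 12–40 syllable databases with 6–15 probes for stereotypy, and
200 null + 100 signal simulations for the antidromic calibration/power
check.

## Known limitations

* The SAP-style features follow the published *descriptions* of the
  features, not the original implementation's exact formulas; absolute
  score values are therefore not interchangeable with SAP scores, though
  orderings are.
* The imitation-capacity scale constants apply to scores from the original
  scoring pipeline on real song; use locally calibrated constants for
  other feature sets or synthetic material.
* `detect_latency_duration` assumes an excitatory or inhibitory *step*
  change detectable in 2 ms bins; slowly ramping responses will register
  late latencies.
* The WAV reader supports mono PCM16/float32 only, by design.
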