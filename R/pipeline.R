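# Pipeline driver: a validated flat config, four pipelines (imitation,
# stereotypy, neural, simulate), TSV outputs and a JSON run manifest.
# All randomness flows from config seeds.

config_keys <- c(
  # shared
  "seed", "out", "out_dir", "band_lo_hz", "band_hi_hz",
  # audio/features
  "window_ms", "step_ms", "n_tapers", "bandwidth_param",
  "segment_threshold_db", "min_syllable_ms", "min_gap_ms",
  # imitation
  "tutor_wav", "tutor_segments", "pupil_dir", "pupil_wavs", "stride_ms",
  "tau", "capacity_control_mean", "capacity_unrelated_mean",
  # stereotypy
  "syllable_dir", "n_select", "n_sample", "exclude_self", "percentile_method",
  # neural
  "spikes_file", "events_file", "recording_span_ms", "n_shuffles",
  "half_window_ms", "bootstrap_bin_ms", "latency_bin_ms",
  "trials_file", "reference_file", "n_split",
  # simulate
  "distortion", "n_bouts", "n_motifs", "sample_rate",
  "baseline_rate", "latency_ms", "amplitude", "duration_ms", "span_ms")

#' Build and validate a run configuration
#'
#' Unknown keys are rejected by name so typos never silently fall back to
#' defaults.
#'
#' @param ... key = value pairs (see `songeval:::config_keys`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(!nzchar(names(cfg))))) {
    stop_songeval("all config entries must be named", "songeval_config_error")
  }
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) {
    stop_songeval(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "songeval_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Read a YAML config file
#'
#' @param path YAML file of flat key = value pairs.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path),
              "songeval_io_error")
  do.call(run_config, yaml::read_yaml(path))
}

cfg_get <- function(cfg, key, default) cfg[[key]] %||% default

band_of <- function(cfg) c(cfg_get(cfg, "band_lo_hz", default_band[1]),
                           cfg_get(cfg, "band_hi_hz", default_band[2]))

write_manifest <- function(cfg, pipeline, outputs, counts, dir) {
  resolved <- cfg[order(names(cfg))]
  tmp <- tempfile()
  jsonlite::write_json(resolved, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "songeval",
    version = as.character(utils::packageVersion("songeval")),
    pipeline = pipeline,
    seed = cfg_get(cfg, "seed", NULL),
    config = resolved,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = outputs,
    counts = counts)
  unlink(tmp)
  path <- file.path(dir, sprintf("%s_manifest.json", pipeline))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Run a named analysis pipeline
#'
#' Binds the package's stages into the four pipelines.  Outputs are
#' deterministic given config + seed; each run writes machine-readable TSV
#' results plus a JSON manifest recording the resolved config, its hash and
#' per-stage counts.
#'
#' * `imitation`: tutor WAV + segment TSV vs a directory (or list) of pupil
#'   bout WAVs; one result row with acoustic, sequence, imitation, capacity
#'   and loss.
#' * `stereotypy`: a directory of syllable WAVs; stereotypy statistic.
#' * `neural`: spike-time file + event TSV; window test, bootstrap
#'   significance, latency and duration.
#' * `simulate`: synthetic song bouts (WAV + segment TSVs + ground-truth
#'   JSON) and a synthetic spike train.
#'
#' @param config a `run_config` (or list accepted by [run_config()]).
#' @param pipeline one of `"imitation"`, `"stereotypy"`, `"neural"`,
#'   `"simulate"`.
#' @return list with `results` (data.frame), `output_files`, `manifest`.
#' @export
run_pipeline <- function(config,
                         pipeline = c("imitation", "stereotypy", "neural",
                                      "simulate")) {
  pipeline <- match.arg(pipeline)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out_dir <- cfg_get(config, "out_dir", dirname(cfg_get(config, "out", ".")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- switch(pipeline,
                imitation = pipeline_imitation(config),
                stereotypy = pipeline_stereotypy(config),
                neural = pipeline_neural(config),
                simulate = pipeline_simulate(config, out_dir))
  out <- cfg_get(config, "out",
                 file.path(out_dir, paste0(pipeline, "_results.tsv")))
  write_tsv(res$results, out)
  manifest <- write_manifest(config, pipeline,
                             outputs = c(out, res$extra_outputs),
                             counts = res$counts, dir = out_dir)
  message(sprintf("[songeval] %s: %s", pipeline,
                  paste(sprintf("%s=%s", names(res$counts), res$counts),
                        collapse = " ")))
  list(results = res$results, output_files = c(out, res$extra_outputs),
       manifest = manifest)
}

load_track <- function(path, cfg) {
  extract_features(read_wav(path), band = band_of(cfg),
                   window_ms = cfg_get(cfg, "window_ms", 10),
                   step_ms = cfg_get(cfg, "step_ms", 1),
                   n_tapers = cfg_get(cfg, "n_tapers", 2),
                   bandwidth_param = cfg_get(cfg, "bandwidth_param", 1.5))
}

pipeline_imitation <- function(cfg) {
  assert_that(!is.null(cfg$tutor_wav) && !is.null(cfg$tutor_segments),
              "imitation pipeline needs tutor_wav and tutor_segments",
              "songeval_config_error")
  pupils <- cfg$pupil_wavs %||%
    list.files(cfg$pupil_dir %||%
                 stop_songeval("imitation pipeline needs pupil_dir or pupil_wavs",
                               "songeval_config_error"),
               pattern = "\\.wav$", full.names = TRUE)
  assert_that(length(pupils) >= 1, "no pupil WAV files found",
              "songeval_io_error")
  motif <- tutor_motif(load_track(cfg$tutor_wav, cfg),
                       read_segments(cfg$tutor_segments))
  bouts <- lapply(pupils, load_track, cfg = cfg)
  res <- imitation_score(bouts, motif,
                         stride_ms = cfg_get(cfg, "stride_ms", NULL),
                         tau = cfg_get(cfg, "tau", NULL))
  scale <- capacity_scale(cfg_get(cfg, "capacity_control_mean", 0.197),
                          cfg_get(cfg, "capacity_unrelated_mean", 0.104))
  cap <- imitation_capacity(res, scale)
  list(results = data.frame(acoustic_score = res$acoustic_score,
                            sequence_score = res$sequence_score,
                            imitation_score = res$imitation_score,
                            capacity = cap$capacity_fraction,
                            loss = cap$loss_fraction,
                            n_bouts = res$n_bouts),
       counts = c(bouts_scored = res$n_bouts), extra_outputs = character(0))
}

pipeline_stereotypy <- function(cfg) {
  assert_that(!is.null(cfg$syllable_dir),
              "stereotypy pipeline needs syllable_dir", "songeval_config_error")
  files <- list.files(cfg$syllable_dir, pattern = "\\.wav$", full.names = TRUE)
  assert_that(length(files) >= 2, "need >= 2 syllable WAV files",
              "songeval_io_error")
  db <- lapply(files, read_wav)
  res <- syllable_stereotypy(
    db, n_select = cfg_get(cfg, "n_select", min(100, length(db))),
    n_sample = cfg_get(cfg, "n_sample", 100),
    seed = cfg_get(cfg, "seed", NULL),
    exclude_self = cfg_get(cfg, "exclude_self", TRUE),
    percentile_method = cfg_get(cfg, "percentile_method", "linear"),
    band_hz = band_of(cfg))
  list(results = data.frame(stereotypy = res$stereotypy,
                            n_selected = res$n_selected,
                            n_sampled = res$n_sampled_per_selected,
                            n_syllables = length(db)),
       counts = c(syllables = length(db), probes = res$n_selected),
       extra_outputs = character(0))
}

pipeline_neural <- function(cfg) {
  assert_that(!is.null(cfg$spikes_file) && !is.null(cfg$events_file),
              "neural pipeline needs spikes_file and events_file",
              "songeval_config_error")
  st_times <- read_spike_times(cfg$spikes_file)
  events <- read_events(cfg$events_file)
  span <- cfg_get(cfg, "recording_span_ms",
                  c(0, max(c(st_times, events$onsets)) + 2000))
  spikes <- spike_train(st_times, span)
  wt <- window_count_test(spikes, events,
                          half_window_ms = cfg_get(cfg, "half_window_ms", 150))
  bs <- circular_shift_bootstrap(
    spikes, events, n_shuffles = cfg_get(cfg, "n_shuffles", 1000),
    bin_width_ms = cfg_get(cfg, "bootstrap_bin_ms", 10),
    seed = cfg_get(cfg, "seed", NULL))
  ld <- tryCatch(
    detect_latency_duration(build_psth(spikes, events,
                                       window = c(-1000, 1000),
                                       bin_width_ms = 2)),
    songeval_degenerate_error = function(e)
      list(latency_ms = NA_real_, duration_ms = NA_real_, flagged = TRUE))
  list(results = data.frame(window_test_p = wt$p_value,
                            bootstrap_p = bs$bootstrap_p,
                            significant = bs$significant,
                            latency_ms = ld$latency_ms,
                            duration_ms = ld$duration_ms,
                            n_events = bs$n_events),
       counts = c(events_used = bs$n_events,
                  shuffles_run = cfg_get(cfg, "n_shuffles", 1000)),
       extra_outputs = character(0))
}

pipeline_simulate <- function(cfg, out_dir) {
  seed <- cfg_get(cfg, "seed", 1)
  g <- generate_song(song_template(),
                     distortion_spec(cfg_get(cfg, "distortion", 0)),
                     n_bouts = cfg_get(cfg, "n_bouts", 3),
                     n_motifs = cfg_get(cfg, "n_motifs", 3),
                     sample_rate = cfg_get(cfg, "sample_rate", 40000),
                     seed = seed)
  wavs <- character(0)
  for (b in seq_along(g$bouts)) {
    wav <- file.path(out_dir, sprintf("bout_%02d.wav", b))
    write_wav(g$bouts[[b]], wav)
    seg <- file.path(out_dir, sprintf("bout_%02d_segments.tsv", b))
    write_segments(g$segments[[b]], seg)
    wavs <- c(wavs, wav, seg)
  }
  ev <- noise_burst_events(20)
  spec <- response_spec(baseline_rate = cfg_get(cfg, "baseline_rate", 5),
                        latency_ms = cfg_get(cfg, "latency_ms", 24),
                        amplitude = cfg_get(cfg, "amplitude", 60),
                        duration_ms = cfg_get(cfg, "duration_ms", 90))
  span <- cfg_get(cfg, "span_ms", max(ev$onsets) + 2000)
  spikes <- generate_spike_train(ev, spec, span, seed = seed + 1)
  spk <- file.path(out_dir, "unit.txt")
  write_spike_times(spikes, spk)
  evf <- file.path(out_dir, "bursts.tsv")
  write_events(ev, evf)
  truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(seed = seed,
                            distortion = cfg_get(cfg, "distortion", 0),
                            response = unclass(spec)),
                       truth, auto_unbox = TRUE, digits = NA, null = "null")
  list(results = data.frame(n_bouts = length(g$bouts),
                            n_spikes = length(spikes$spike_times),
                            n_events = length(ev$onsets)),
       counts = c(bouts = length(g$bouts),
                  spikes = length(spikes$spike_times)),
       extra_outputs = c(wavs, spk, evf, truth))
}
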