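# PSTHs, window tests, circular-shift bootstrap, latency/duration and
# motif-locked modulation.

test_that("PSTH counts respect boundary conventions and Poisson expectations", {
  ev <- noise_burst_events(5, interval_ms = 3000)
  empty <- spike_train(numeric(0), c(0, 20000))
  p0 <- build_psth(empty, ev)
  expect_true(all(p0$counts == 0))

  # one spike exactly at an event onset lands in the first post-onset bin
  one <- spike_train(ev$onsets[2], c(0, 20000))
  p1 <- build_psth(one, ev, window = c(-1000, 1000), bin_width_ms = 10)
  hit <- which(p1$counts == 1)
  expect_length(hit, 1L)
  expect_equal(p1$bin_edges[hit], 0)

  # homogeneous Poisson rate recovery: mean rate within 3 SE of 10 Hz
  ev200 <- noise_burst_events(200, interval_ms = 2200)
  span <- max(ev200$onsets) + 1500
  st <- generate_spike_train(ev200, response_spec(10, 0, 0, 1), span,
                             seed = 61)
  p <- build_psth(st, ev200, c(-1000, 1000), 10)
  total_s <- p$n_events * 2
  se <- sqrt(10 / total_s)
  expect_lt(abs(mean(p$rate) - 10), 3 * se)

  expect_error(build_psth(empty, event_times(1e6), c(-1000, 1000)),
               class = "songeval_no_events_error")
})

test_that("paired window test matches the closed-form t computation", {
  # 6 events with hand-chosen pre/post counts
  pre_counts <- c(2, 3, 1, 4, 2, 3)
  post_counts <- c(5, 4, 6, 4, 7, 5)
  onsets <- 1000 + (0:5) * 1000
  spikes <- sort(unlist(lapply(1:6, function(i) {
    c(onsets[i] - seq_len(pre_counts[i]) * 10,
      onsets[i] + seq_len(post_counts[i]) * 10)
  })))
  st <- spike_train(spikes, c(0, 8000))
  res <- window_count_test(st, event_times(onsets), half_window_ms = 150)
  d <- post_counts - pre_counts
  t_stat <- mean(d) / (stats::sd(d) / sqrt(6))
  expect_equal(res$statistic, t_stat, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), 5), tolerance = 1e-12)

  # identical pre/post counts -> degenerate, p = 1, flagged
  sym <- sort(unlist(lapply(onsets, function(o) c(o - c(10, 20), o + c(10, 20)))))
  res0 <- window_count_test(spike_train(sym, c(0, 8000)), event_times(onsets))
  expect_equal(res0$p_value, 1)
  expect_true(res0$flagged)
})

test_that("window test detects an injected transient", {
  ev <- noise_burst_events(50, interval_ms = 2500)
  span <- max(ev$onsets) + 1500
  st <- generate_spike_train(ev, response_spec(5, 0, 40, 100), span, seed = 62)
  expect_lt(window_count_test(st, ev)$p_value, 0.001)
})

test_that("bootstrap p matches the closed-form cluster probability", {
  # clusters of 3 and 2 spikes right after two events, one window-sized post
  # bin: a shifted cluster lands post with probability 1/2, so
  # P(null peak >= real peak = 5) = 1/4
  onsets <- c(2000, 6000)
  st <- spike_train(c(2000.5, 2001, 2001.5, 6000.5, 6001), c(0, 9000))
  r <- circular_shift_bootstrap(st, event_times(onsets), n_shuffles = 4000,
                                bin_width_ms = 1000, seed = 63)
  expect_lt(abs(r$bootstrap_p - 0.25), 0.03)   # ~4 SE of the shuffle MC

  # single cluster: P(null >= 3) ~ 1/2
  st1 <- spike_train(c(2000.5, 2001, 2001.5), c(0, 5000))
  r1 <- circular_shift_bootstrap(st1, event_times(2000), n_shuffles = 4000,
                                 bin_width_ms = 1000, seed = 64)
  expect_lt(abs(r1$bootstrap_p - 0.5), 0.04)

  # empty train: non-significant with p = 1
  r_empty <- circular_shift_bootstrap(spike_train(numeric(0), c(0, 5000)),
                                      event_times(2000), n_shuffles = 50,
                                      seed = 65)
  expect_equal(r_empty$bootstrap_p, 1)
  expect_false(r_empty$significant)
  expect_true(r_empty$flagged)
})

test_that("bootstrap is seed-reproducible and offset-invariant", {
  ev <- noise_burst_events(30, interval_ms = 2500)
  span <- max(ev$onsets) + 1500
  st <- generate_spike_train(ev, response_spec(8, 20, 30, 80), span, seed = 66)
  a <- circular_shift_bootstrap(st, ev, n_shuffles = 100, seed = 7)
  b <- circular_shift_bootstrap(st, ev, n_shuffles = 100, seed = 7)
  expect_identical(a$null_peak_rates, b$null_peak_rates)
  expect_identical(a$bootstrap_p, b$bootstrap_p)

  shifted <- spike_train(st$spike_times + 500,
                         st$recording_span + 500)
  ev_shifted <- event_times(ev$onsets + 500, ev$offsets + 500,
                            kind = ev$kind)
  c_ <- circular_shift_bootstrap(shifted, ev_shifted, n_shuffles = 100,
                                 seed = 7)
  expect_equal(c_$bootstrap_p, a$bootstrap_p)
  expect_equal(c_$real_peak_rate, a$real_peak_rate)
})

test_that("bootstrap detects an injected response", {
  ev <- noise_burst_events(60, interval_ms = 2500)
  span <- max(ev$onsets) + 1500
  st <- generate_spike_train(ev, response_spec(5, 24, 60, 90), span, seed = 67)
  r <- circular_shift_bootstrap(st, ev, n_shuffles = 500, seed = 68)
  expect_true(r$significant)
  expect_lt(r$bootstrap_p, 0.01)
})

test_that("averaged-response significance behaves at its fixed points", {
  ev <- noise_burst_events(40, interval_ms = 2500)
  span <- max(ev$onsets) + 1500
  zero <- build_psth(spike_train(numeric(0), c(0, span)), ev)
  r0 <- average_response_significance(list(zero, zero), n_shuffles = 50,
                                      seed = 70)
  expect_equal(r0$p_value, 1)

  psths <- lapply(1:10, function(u)
    build_psth(generate_spike_train(ev, response_spec(5, 25, 20, 50), span,
                                    seed = 700 + u), ev))
  r <- average_response_significance(psths, n_shuffles = 400, seed = 71)
  expect_lt(r$p_value, 0.01)
  expect_gte(r$p_value, r$p_peak)
  expect_gte(r$p_value, r$p_count)
  expect_error(average_response_significance(psths[1]),
               class = "songeval_validation_error")
})

test_that("latency/duration follow the consecutive-bin rule on a crafted PSTH", {
  # baseline bins alternate 2/4 counts; post bins 4..8 are strongly
  # significant; everything after is baseline-like -> latency = 6 ms and the
  # response ends at bin 9 (left edge 16 ms): duration 10 ms
  edges <- seq(-1000, 1000, by = 2)
  nb <- length(edges) - 1
  counts <- rep(c(2, 4), length.out = nb)
  left <- edges[-length(edges)]
  post <- which(left >= 0)
  counts[post[4:8]] <- 60
  psth <- structure(list(bin_edges = edges, counts = counts,
                         rate = counts / (100 * 0.002), n_events = 100,
                         bin_width_ms = 2), class = "psth")
  r <- detect_latency_duration(psth)
  expect_equal(r$latency_ms, 6)
  expect_equal(r$duration_ms, 16 - 6)

  # flat PSTH: no latency
  flat <- psth
  flat$counts <- rep(c(2, 4), length.out = nb)
  rf <- detect_latency_duration(flat)
  expect_true(is.na(rf$latency_ms))
  expect_true(rf$flagged)

  # zero-variance baseline is rejected
  const <- psth
  const$counts <- rep(3, nb)
  expect_error(detect_latency_duration(const),
               class = "songeval_degenerate_error")
})

test_that("latency/duration recover injected rectangular responses", {
  ev <- noise_burst_events(200, interval_ms = 2500)
  span <- max(ev$onsets) + 1500
  ok <- 0
  for (s in 1:5) {
    st <- generate_spike_train(ev, response_spec(5, 24, 60, 90), span,
                               seed = 800 + s)
    r <- detect_latency_duration(build_psth(st, ev, c(-1000, 1000), 2))
    if (!is.na(r$latency_ms) && abs(r$latency_ms - 24) <= 4 &&
          !is.na(r$duration_ms) && abs(r$duration_ms - 90) <= 10) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("motif-locked modulation separates locked from unlocked firing", {
  mot <- event_times(seq(1000, by = 1500, length.out = 30),
                     seq(1000, by = 1500, length.out = 30) + 600,
                     kind = "motif")
  locked <- generate_spike_train(event_times(mot$onsets),
                                 response_spec(5, 100, 40, 80), 50000,
                                 seed = 81)
  r_locked <- motif_locked_modulation(locked, mot, n_shuffles = 400,
                                      seed = 82)
  expect_lt(r_locked$p_value, 0.01)

  # a single spike per motif at an identical phase is maximally locked
  st1 <- spike_train(mot$onsets + 123.4, c(0, 50000))
  r1 <- motif_locked_modulation(st1, mot, n_shuffles = 400, seed = 83)
  expect_lte(r1$p_value, 1 / 400 + 0.02)

  expect_error(motif_locked_modulation(locked, event_times(mot$onsets)),
               class = "songeval_validation_error")
})

test_that("motif-locked type-I error is nominal under Poisson firing", {
  mot <- event_times(seq(1000, by = 1200, length.out = 40),
                     seq(1000, by = 1200, length.out = 40) + 600,
                     kind = "motif")
  hits <- 0
  n_units <- 150
  for (u in seq_len(n_units)) {
    st <- generate_spike_train(event_times(mot$onsets),
                               response_spec(10, 0, 0, 1), 50000,
                               seed = 900 + u)
    r <- motif_locked_modulation(st, mot, n_shuffles = 200, seed = 2000 + u)
    if (r$mid_p < 0.05) hits <- hits + 1
  }
  ci <- stats::qbinom(c(0.005, 0.995), n_units, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
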