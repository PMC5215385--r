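test_that("spike train generation respects rates, burst rules and seeds", {
  # zero rates -> empty train
  tr0 <- generate_spike_train(50, single_ap_rate = 0, burst_rate = 0, seed = 1)
  expect_length(tr0$times, 0)

  # parameter validation
  expect_error(generate_spike_train(-10), "duration")
  expect_error(generate_spike_train(10, single_ap_rate = -1), "rates")
  expect_error(generate_spike_train(10, intra_burst_isi = 0.2), "intra_burst_isi")

  # Poisson count oracle: 2 Hz singles over 100 s; the gap construction
  # preserves the Poisson count, so the sample mean must sit near 200
  counts <- vapply(1:300, function(s) {
    length(generate_spike_train(100, single_ap_rate = 2, burst_rate = 0,
                                seed = s)$times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200) / sqrt(300))
  expect_gte(mean(abs(counts - 200) <= 3 * sqrt(200)), 0.99)

  # deterministic bursts: probs force 3-AP bursts, both ISIs < 100 ms
  tr3 <- generate_spike_train(200, single_ap_rate = 0, burst_rate = 0.05,
                              burst_size_probs = c(0, 0, 1, 0),
                              intra_burst_isi = 0.03, seed = 4)
  ev <- classify_bursts(tr3)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$n_aps == 3L))
  expect_true(all(diff(tr3$times)[diff(tr3$times) < 0.1] < 0.1))

  # singles separated >= 100 ms from any other spike
  trs <- generate_spike_train(100, single_ap_rate = 1.5, burst_rate = 0.1,
                              seed = 9)
  evs <- classify_bursts(trs)
  expect_true(all(diff(evs$onset_s) >= 0.1))

  # bit-reproducible under a fixed seed
  expect_identical(generate_spike_train(60, seed = 42)$times,
                   generate_spike_train(60, seed = 42)$times)
})

test_that("spike-to-fluorescence kernel superposition is linear and peaks correctly", {
  k <- transient_kernel(amplitude_per_ap = 1, tau_up = 0.05, tau_down = 0.5,
                        onset_delay = 0)
  fs <- 1000

  # no spikes -> identically zero
  expect_identical(spikes_to_fluorescence(spike_train(numeric(0), 5), k, fs),
                   numeric(5000))

  # single-spike peak location/value against a numerical-optimization oracle
  x <- spikes_to_fluorescence(spike_train(1, 10), k, fs)
  opt <- optimize(function(t) kernel_eval(k, t), c(0, 3), maximum = TRUE)
  expect_equal(max(x), opt$objective, tolerance = 1e-5)
  expect_equal((which.max(x) - 1) / fs - 1, opt$maximum, tolerance = 2 / fs)
  # closed-form maximum of the rise-decay product
  tu <- k$tau_up; td <- k$tau_down
  peak_cf <- (td / (tu + td)) * (tu / (tu + td))^(tu / td)
  expect_equal(max(x), peak_cf, tolerance = 1e-5)

  # additivity: two spikes 10 s apart equal the sum of shifted singles
  x2 <- spikes_to_fluorescence(spike_train(c(1, 11), 20), k, fs)
  xa <- spikes_to_fluorescence(spike_train(1, 20), k, fs)
  xb <- spikes_to_fluorescence(spike_train(11, 20), k, fs)
  expect_equal(x2, xa + xb, tolerance = 1e-12)

  # linearity on random trains: union of trains = sum of traces
  set.seed(5)
  ta <- sort(runif(8, 0, 20)); tb <- sort(runif(7, 0, 20))
  xu <- spikes_to_fluorescence(spike_train(sort(c(ta, tb)), 25), k, 200)
  xs <- spikes_to_fluorescence(spike_train(ta, 25), k, 200) +
    spikes_to_fluorescence(spike_train(tb, 25), k, 200)
  expect_equal(xu, xs, tolerance = 1e-12)
})

test_that("noise/baseline synthesis produces calibrated digits", {
  flat <- numeric(2000)
  # zero noise, zero drift -> constant baseline
  expect_equal(add_noise_and_baseline(flat, 100, 0, 500), rep(500, 2000))
  expect_error(add_noise_and_baseline(flat, 100, -1, 500), "noise_sd")
  expect_error(add_noise_and_baseline(flat, 100, 1, 0), "f0_level")

  # sampling oracle: sample sd of a flat noisy trace within 5% at 1e5
  y <- add_noise_and_baseline(numeric(1e5), 1000, 3, 500, seed = 2)
  expect_lt(abs(sd(y) - 3) / 3, 0.05)

  # linear drift of 1%/min recovered by baseline_change
  fs <- 100; dur <- 120
  dr <- function(t) 500 * 0.01 * t / 60
  y <- add_noise_and_baseline(numeric(dur * fs), fs, 0, 500, drift = dr)
  bc <- baseline_change(y, fs, c(0, 0.5), c(119.5, 120))
  expect_equal(bc, 0.01 * (119.75 - 0.25) / 60, tolerance = 1e-3)
})

test_that("population generator controls synchrony and participation", {
  k <- transient_kernel()
  # perfect synchrony: no jitter, full participation, no noise -> r = 1
  pop <- generate_population(4, 30, network_event_rate = 0.2,
                             participation_prob = 1, onset_jitter_sd = 0,
                             independent_rate = 0, noise_sd = 0,
                             kernel = k, fs = 200, seed = 3)
  expect_gt(length(pop$network_events), 0)
  M <- pairwise_correlation(pop$traces, tau = NULL)
  expect_equal(unname(M[upper.tri(M)]), rep(1, 6), tolerance = 1e-12)

  # independent events only -> near-zero mean pairwise correlation
  pop0 <- generate_population(10, 60, network_event_rate = 0,
                              independent_rate = 0.3, noise_sd = 0.02,
                              kernel = k, fs = 200, seed = 8)
  M0 <- pairwise_correlation(pop0$traces, tau = 0.015)
  expect_lt(abs(network_correlation(M0)), 0.05)

  # binomial participation: per-cell recruited events ~ p * n_network
  pop5 <- generate_population(40, 100, network_event_rate = 0.3,
                              participation_prob = 0.5, onset_jitter_sd = 0,
                              independent_rate = 0, noise_sd = 0,
                              kernel = k, fs = 100, seed = 11)
  n_net <- length(pop5$network_events)
  per_cell <- vapply(pop5$spike_trains, function(tr) length(tr$times),
                     numeric(1))
  p_hat <- mean(per_cell) / n_net
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / (40 * n_net)))

  # network correlation rises monotonically as jitter -> 0
  r_at_jitter <- vapply(c(0.08, 0.02, 0), function(j) {
    p <- generate_population(6, 40, network_event_rate = 0.25,
                             participation_prob = 1, onset_jitter_sd = j,
                             independent_rate = 0, noise_sd = 0.02,
                             kernel = k, fs = 200, seed = 21)
    network_correlation(pairwise_correlation(p$traces))
  }, numeric(1))
  expect_true(all(diff(r_at_jitter) > 0))
  expect_gt(r_at_jitter[3], 0.9)
})

test_that("crosstalk mixing is linear, conservative and validated", {
  k <- transient_kernel()
  pop <- generate_population(3, 20, network_event_rate = 0.2,
                             independent_rate = 0.2, noise_sd = 0,
                             kernel = k, fs = 100, seed = 6)
  ts <- pop$traces

  # identity matrix leaves traces unchanged
  expect_equal(apply_crosstalk(ts, diag(3))$traces, ts$traces)

  # single off-diagonal coefficient: contaminated peak = 0.07 x source peak
  silent <- trace_set(rbind(ts$traces[1, ], 0 * ts$traces[2, ]), ts$fs)
  C <- diag(2); C[1, 2] <- 0.07
  mixed <- apply_crosstalk(silent, C)
  expect_equal(max(mixed$traces[2, ]), 0.07 * max(silent$traces[1, ]),
               tolerance = 1e-12)

  # linearity in the input traces
  set.seed(2)
  C3 <- diag(3); C3[upper.tri(C3)] <- runif(3, 0, 0.2)
  a <- ts; b <- ts; b$traces <- b$traces[3:1, ]
  ab <- ts; ab$traces <- a$traces + b$traces
  expect_equal(apply_crosstalk(ab, C3)$traces,
               apply_crosstalk(a, C3)$traces + apply_crosstalk(b, C3)$traces,
               tolerance = 1e-12)

  # mixing convention against an explicit double-loop oracle, and signal
  # conservation: total output = sum_j rowSums(C)_j * trace_j, so each
  # unit of source signal is distributed according to its row of C
  mixedC <- apply_crosstalk(ts, C3)$traces
  oracle <- matrix(0, 3, ncol(ts$traces))
  for (i in 1:3) for (j in 1:3) {
    oracle[i, ] <- oracle[i, ] + C3[j, i] * ts$traces[j, ]
  }
  expect_equal(unname(mixedC), oracle, tolerance = 1e-12)
  expect_equal(colSums(mixedC),
               colSums(rowSums(C3) * ts$traces), tolerance = 1e-12)

  # dimension mismatch rejected
  expect_error(apply_crosstalk(ts, diag(2)), "dimension")
})

test_that("light artifacts are additive square pulses in valid epochs", {
  fs <- 500
  x <- numeric(10 * fs)
  # zero amplitude is the identity
  expect_equal(inject_light_artifact(x, fs, cbind(2, 1), 0), x)
  # overlapping epochs rejected
  expect_error(inject_light_artifact(x, fs, rbind(c(2, 1), c(2.5, 1)), 1),
               "non-overlapping")
  expect_error(inject_light_artifact(x, fs, cbind(9.5, 1), 1), "inside")

  # amplitude 5 sigma on flat noise: measured event SNR ~ 5
  set.seed(3)
  noise <- rnorm(10 * fs, 0, 0.02)
  y <- inject_light_artifact(noise, fs, cbind(4, 1), 5 * 0.02)
  snr <- event_snr(y, fs, t_peak = 4.5, baseline_window = c(1, 3))
  expect_gt(snr, 3.5); expect_lt(snr, 6.5)
})
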