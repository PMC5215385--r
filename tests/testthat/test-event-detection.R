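test_that("noise sd is recovered by the zero-centred Gaussian fit", {
  set.seed(1)
  # i.i.d. N(0, 1): sigma within 2%
  x <- rnorm(1e5)
  expect_lt(abs(estimate_sigma(x)$sigma - 1), 0.02)

  # homogeneity: scaling the signal scales sigma
  s1 <- estimate_sigma(x)$sigma
  s3 <- estimate_sigma(3 * x)$sigma
  expect_equal(s3 / s1, 3, tolerance = 0.02)

  # robustness to 1% large positive outliers (transient-like upper tail)
  xc <- x
  idx <- sample(length(x), 1000)
  xc[idx] <- abs(xc[idx]) + 8
  expect_lt(abs(estimate_sigma(xc)$sigma - s1) / s1, 0.05)

  expect_error(estimate_sigma(numeric(2000)), "all-zero")
  expect_error(estimate_sigma(rnorm(100)), "1000 samples")
})

test_that("event detection controls false positives and finds transients", {
  fs <- 1000
  # pure noise at 5 sigma: no events in >= 95% of seeded runs
  n_events <- vapply(1:100, function(s) {
    set.seed(s)
    nrow(detect_events(rnorm(30 * fs, 0, 0.05), fs, threshold_sigma = 5,
                       fit_onsets = FALSE))
  }, numeric(1))
  expect_gte(mean(n_events == 0), 0.95)

  # one strong transient (amplitude 10x noise sd): exactly one event
  k <- transient_kernel(amplitude_per_ap = 0.5, tau_up = 0.05,
                        tau_down = 0.5, onset_delay = 0)
  x1 <- synth_trace(20, fs, 8, noise_sd = 0.05, seed = 7, kernel = k)
  ev1 <- detect_events(x1, fs, fit_onsets = FALSE)
  expect_equal(nrow(ev1), 1L)
  expect_lt(abs(ev1$peak_s - 8) , 0.5)

  # two threshold crossings 100 ms apart merge into one event
  x2 <- synth_trace(20, fs, c(8, 8.1), noise_sd = 0.05, seed = 7, kernel = k)
  ev2 <- detect_events(x2, fs, fit_onsets = FALSE)
  expect_equal(nrow(ev2), 1L)

  # crossings beyond the refractory time stay separate
  x3 <- synth_trace(20, fs, c(8, 9.5), noise_sd = 0.05, seed = 7, kernel = k)
  ev3 <- detect_events(x3, fs, fit_onsets = FALSE)
  expect_equal(nrow(ev3), 2L)

  expect_error(detect_events(rnorm(100 * 10), 10), "too low")
  expect_error(detect_events(rnorm(30000), 1000, threshold_sigma = 6),
               "threshold_sigma")
})

test_that("event count is monotone in threshold and respects the refractory", {
  fs <- 500
  set.seed(12)
  spikes <- sort(runif(30, 1, 58))
  k <- transient_kernel(amplitude_per_ap = 0.25, tau_up = 0.04,
                       tau_down = 0.4, onset_delay = 0)
  x <- synth_trace(60, fs, spikes[c(TRUE, diff(spikes) > 0.05)],
                   noise_sd = 0.05, seed = 5, kernel = k)
  counts <- vapply(c(4, 4.5, 5), function(th) {
    nrow(detect_events(x, fs, threshold_sigma = th, fit_onsets = FALSE))
  }, numeric(1))
  expect_gt(counts[1], 0)
  expect_true(all(diff(counts) <= 0))

  # hard refractory assertion: no two accepted events closer than 150 ms
  for (th in c(4, 4.5, 5)) {
    ev <- detect_events(x, fs, threshold_sigma = th, fit_onsets = FALSE)
    if (nrow(ev) > 1) {
      expect_true(all(diff(sort(ev$detect_s)) >= 0.15 - 1e-9))
    }
  }
})

test_that("four-parameter transient fit recovers generating parameters", {
  fs <- 1000
  tt <- (0:3000) / fs
  kshape <- function(t, A, t0, tu, td) {
    ifelse(t >= t0, A * (1 - exp(-(t - t0) / tu)) * exp(-(t - t0) / td), 0)
  }

  # noiseless curve: relative error < 1e-4 on all parameters
  y <- kshape(tt, 1, 0.1, 0.05, 0.5)
  f <- fit_transient(y, fs, t_peak = 0.25)
  expect_lt(abs(f$A - 1), 1e-4)
  expect_lt(abs(f$t0 - 0.1), 1e-4)
  expect_lt(abs(f$tau_up - 0.05) / 0.05, 1e-4)
  expect_lt(abs(f$tau_down - 0.5) / 0.5, 1e-4)

  # tau_down beyond its bound: fit saturates at 5 s
  y10 <- kshape((0:8000) / fs, 1, 0.1, 0.05, 10)
  f10 <- fit_transient(y10, fs, t_peak = 0.4, window = c(0.5, 7))
  expect_equal(f10$tau_down, 5, tolerance = 1e-6)

  # 10% noise: onset within 2 samples of the dense grid-search oracle
  set.seed(3)
  yn <- kshape(tt, 1, 0.1, 0.05, 0.5) + rnorm(length(tt), 0, 0.1)
  yn5 <- ewma(yn, 0.005, fs)
  fn <- fit_transient(yn5, fs, t_peak = 0.25)
  t0_oracle <- grid_search_t0(tt, yn5, t0_grid = seq(0.05, 0.2, by = 5e-4))
  expect_lte(abs(fn$t0 - t0_oracle), 2 / fs)

  # consistency: random parameter draws within bounds are recovered;
  # the window must reach back past the onset, so it is wider than the
  # default to accommodate slow-rise draws (onset-to-peak up to ~1.3 s)
  tt6 <- (0:6000) / fs
  set.seed(9)
  for (i in 1:25) {
    A <- runif(1, 0.2, 2); t0 <- runif(1, 0.05, 0.3)
    tu <- runif(1, 0.01, 0.5); td <- runif(1, max(0.1, tu), 3)
    yy <- kshape(tt6, A, t0, tu, td)
    pk <- tt6[which.max(yy)]
    ff <- fit_transient(yy, fs, t_peak = pk, window = c(1.5, 4))
    expect_true(ff$converged)
    expect_lt(abs(ff$t0 - t0), 5e-3)
    expect_lt(abs(ff$A - A) / A, 0.02)
  }
})

test_that("event SNR is the peak over baseline-noise ratio and grows with APs", {
  fs <- 500
  # exact arithmetic: dF = 5 sd -> SNR = 5
  x <- rep(c(1, -1) / 2, 500)           # sd exactly 0.5003 over window
  base_sd <- sd(x[1:500])
  x[800] <- x[800] + 5 * base_sd
  got <- event_snr(x, fs, t_peak = (800 - 1) / fs, baseline_window = c(0, 1))
  expect_equal(got, 5 + (x[800] - 5 * base_sd - mean(x[1:500])) / base_sd,
               tolerance = 1e-10)

  # zero dF -> SNR ~ 0
  flat <- rep(c(0.1, -0.1), 500)
  expect_equal(event_snr(flat, fs, 1.6, c(0, 1)),
               (flat[801] - mean(flat[1:500])) / sd(flat[1:500]))

  # SNR increases with the number of APs per burst (seeded pipeline runs)
  k <- transient_kernel()
  snr_by_ap <- vapply(1:4, function(nap) {
    mean(vapply(1:20, function(s) {
      spikes <- 5 + 0.01 * (0:(nap - 1))
      x <- synth_trace(12, fs, spikes, noise_sd = 0.05, seed = s, kernel = k)
      xf <- ewma(x, 0.015, fs)
      event_snr(xf, fs, t_peak = (which.max(xf) - 1) / fs,
                baseline_window = c(0.5, 4.5))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(snr_by_ap) > 0))

  expect_error(event_snr(flat, fs, 1.6, c(1, 1)), "empty baseline")
})

test_that("greedy spike matching agrees with the exhaustive oracle", {
  # identical lists: full accuracy, zero delays
  m <- match_events(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$detection_accuracy, 1)
  expect_equal(m$delays_ms, c(0, 0, 0))

  # fully disjoint lists (gaps > 100 ms): zero accuracy
  m0 <- match_events(c(1, 2), c(1.5, 2.5))
  expect_equal(m0$detection_accuracy, 0)
  expect_equal(m0$false_positives, 2)

  # 3 ephys, 2 calcium in range: accuracy 2/3
  m23 <- match_events(c(1.02, 2.05), c(1, 2, 3))
  expect_equal(m23$detection_accuracy, 2 / 3)

  # random small cases against the brute-force assignment oracle
  set.seed(6)
  for (i in 1:25) {
    ca <- sort(runif(sample(0:5, 1), 0, 3))
    ep <- sort(runif(sample(1:5, 1), 0, 3))
    got <- match_events(ca, ep)
    oracle <- brute_force_match(ca, ep)
    expect_equal(sum(got$matched), oracle$n)
  }
})

test_that("burst classification follows the 100 ms inter-spike rule", {
  # one isolated spike: one single-AP event
  expect_equal(classify_bursts(spike_train(2, 10)),
               data.frame(onset_s = 2, n_aps = 1L))
  # spikes at 0, 50, 90 ms: one 3-AP burst
  b <- classify_bursts(c(0, 0.05, 0.09))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_aps, 3L)
  # spikes 150 ms apart: two single APs
  s <- classify_bursts(c(0, 0.15))
  expect_equal(s$n_aps, c(1L, 1L))
  # maximal burst-event rate is bounded by 10 Hz
  set.seed(2)
  tr <- generate_spike_train(120, single_ap_rate = 2, burst_rate = 0.5,
                             seed = 31)
  ev <- classify_bursts(tr)
  expect_lte(nrow(ev) / 120, 10)
  expect_true(all(diff(ev$onset_s) >= 0.1))
})

test_that("onset precision reflects the calcium-onset latency and noise", {
  expect_equal(onset_precision(match_events(c(1, 2), c(1, 2)))$mean_ms, 0)
  m <- match_events(c(1.008, 2.008), c(1, 2))
  op <- onset_precision(m)
  expect_equal(op$mean_ms, 8, tolerance = 1e-9)
  expect_equal(op$sd_ms, 0, tolerance = 1e-9)
  expect_error(onset_precision(match_events(1, 2)), "no matched")

  # end-to-end at 1 kHz: positive mean delay; onset sd shrinks as the
  # noise decreases (monotone over 3 noise levels)
  fs <- 1000
  k <- transient_kernel()
  sd_at_noise <- vapply(c(0.08, 0.04, 0.01), function(ns) {
    delays <- unlist(lapply(1:6, function(s) {
      spikes <- c(3, 8, 13)
      x <- synth_trace(16, fs, spikes, noise_sd = ns, seed = 40 + s,
                       kernel = k)
      ev <- detect_events(x, fs, threshold_sigma = 4, fit_onsets = TRUE)
      if (!nrow(ev)) return(numeric(0))
      match_events(sort(ev$onset_s), spikes)$delays_ms
    }))
    c(sd(delays), mean(delays))
  }, numeric(2))
  expect_gt(mean(sd_at_noise[2, ]), 0)          # onset lags the AP
  expect_true(all(diff(sd_at_noise[1, ]) < 0))  # jitter shrinks with noise
})
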