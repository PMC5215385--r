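#' Noise sd of a processed signal via a zero-centred Gaussian fit
#'
#' Builds a histogram of the processed signal (Freedman-Diaconis bin
#' width) and fits a zero-centred Gaussian \code{a exp(-x^2 / (2 s^2))}
#' to the bin counts by least squares. The fit is restricted to bins with
#' centre <= 0 (the mirrored negative side), which makes the estimate
#' robust to the positive-going calcium transients that contaminate the
#' upper tail.
#'
#' @param x processed signal (>= 1000 samples).
#' @return list of class \code{noise_estimate}: \code{sigma},
#'   \code{bin_width}, \code{fit_residual}.
#' @export
estimate_sigma <- function(x) {
  if (length(x) < 1000L) stop("at least 1000 samples are required")
  if (all(x == 0)) stop("all-zero signal: noise sd is degenerate")
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) stop("degenerate signal: zero interquartile range")
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  keep <- h$mids <= 0
  df <- data.frame(mid = h$mids[keep], count = h$counts[keep])
  if (nrow(df) < 3L) stop("too few negative-side bins for the Gaussian fit")
  s0 <- stats::mad(x)
  if (s0 == 0) s0 <- stats::sd(x)
  fit <- minpack.lm::nlsLM(
    count ~ a * exp(-mid^2 / (2 * s^2)), data = df,
    start = list(a = max(df$count), s = s0),
    lower = c(a = 1e-12, s = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(sigma = unname(abs(co["s"])), bin_width = bw,
                 fit_residual = sqrt(mean(stats::resid(fit)^2))),
            class = "noise_estimate")
}

# detection pre-processing: EWMA (tau_filter) -> first derivative ->
# moving average; optional rectification of negatives (40 Hz variant)
.processed_signal <- function(x, fs, tau_filter, deriv_ma_window,
                              rectify_negative) {
  filt <- ewma(x, tau_filter, fs)
  d <- c(0, diff(filt)) * fs
  proc <- moving_average(d, deriv_ma_window, fs)
  if (rectify_negative) proc[proc < 0] <- 0
  list(filtered = filt, processed = proc)
}

#' Detect calcium events on a normalized trace
#'
#' Implements the derivative-threshold pipeline: the trace is filtered
#' with an EWMA (tau = 100 ms), its first derivative is computed and
#' smoothed with a 100 ms simple moving average, the noise sd of the
#' processed signal is estimated with a zero-centred Gaussian fit, and
#' threshold up-crossings above \code{threshold_sigma * sigma} are taken
#' as calcium events with a 150 ms refractory time: a crossing within the
#' refractory time of the previously accepted event is merged into it.
#' For low acquisition rates (<= 40 Hz) negative values of the processed
#' signal can be reset to zero (\code{rectify_negative}), which helps
#' identify events riding on the decay of previous transients. The noise
#' sd is always estimated before rectification.
#'
#' The peak time t1 (argmax of the filtered trace between the crossing
#' and the next sub-threshold return) serves as the initial guess for the
#' event onset, which is refined by the four-parameter transient fit on
#' the trace filtered at tau = 5 ms (\code{fit_onsets = TRUE}).
#'
#' @param x normalized trace (dF/F or dF/bg), >= 3 s.
#' @param fs sampling rate, Hz (>= 20).
#' @param threshold_sigma detection threshold in noise sd units,
#'   conventionally in [4, 5] (default 5).
#' @param tau_filter EWMA decay constant, s (default 0.1).
#' @param deriv_ma_window moving-average window on the derivative, s.
#' @param refractory minimum spacing between accepted events, s.
#' @param rectify_negative reset negative processed values to zero
#'   (40 Hz variant).
#' @param fit_onsets refine onsets with the transient fit (slower).
#' @param baseline_window length of the pre-event baseline used for
#'   amplitude and SNR, s.
#' @return data.frame of class \code{calcium_events} with columns
#'   \code{onset_s} (fitted or crossing-based onset), \code{detect_s}
#'   (threshold-crossing time; the refractory spacing is guaranteed on
#'   these), \code{peak_s}, \code{amplitude}, \code{snr}, and
#'   attributes \code{sigma} (processed-signal noise sd) and
#'   \code{threshold_sigma}.
#' @export
detect_events <- function(x, fs, threshold_sigma = 5,
                          tau_filter = 0.1, deriv_ma_window = 0.1,
                          refractory = 0.15, rectify_negative = FALSE,
                          fit_onsets = TRUE, baseline_window = 0.5) {
  if (fs < 20) stop("`fs` too low for the detection filters (< 20 Hz)")
  if (length(x) < 3 * fs) stop("trace must be at least 3 s long")
  if (threshold_sigma < 4 || threshold_sigma > 5) {
    stop("`threshold_sigma` must lie in [4, 5]")
  }
  pp <- .processed_signal(x, fs, tau_filter, deriv_ma_window,
                          rectify_negative = FALSE)
  sigma <- estimate_sigma(pp$processed)$sigma
  proc <- pp$processed
  if (rectify_negative) proc[proc < 0] <- 0
  thr <- threshold_sigma * sigma

  above <- proc >= thr
  cross <- which(above & !c(FALSE, above[-length(above)]))
  # blank the filter settling region: truncated edge windows inflate the
  # processed-signal variance and would fabricate edge events
  settle <- 3 * tau_filter + deriv_ma_window / 2
  t_cross_all <- (cross - 1L) / fs
  cross <- cross[t_cross_all >= settle &
                 t_cross_all <= length(x) / fs - deriv_ma_window / 2]
  events <- list()
  last_t <- -Inf
  for (ci in cross) {
    t_cross <- (ci - 1L) / fs
    if (t_cross - last_t < refractory) next  # merged into previous event
    ret <- ci + which(!above[ci:length(above)])[1L] - 1L
    if (is.na(ret)) ret <- length(x)
    seg <- ci:ret
    pk <- seg[which.max(pp$filtered[seg])]
    t_peak <- (pk - 1L) / fs
    # pre-event baseline on the filtered trace
    b1 <- max(1L, ci - round(baseline_window * fs))
    b2 <- max(b1, ci - 1L)
    base <- pp$filtered[b1:b2]
    dF <- pp$filtered[pk] - mean(base)
    base_sd <- if (length(base) > 1L) stats::sd(base) else NA_real_
    snr <- if (is.finite(base_sd) && base_sd > 0) dF / base_sd else NA_real_
    onset <- t_cross
    if (fit_onsets) {
      tf <- fit_transient(ewma(x, 0.005, fs), fs, t_peak)
      if (isTRUE(tf$converged)) onset <- tf$t0
    }
    events[[length(events) + 1L]] <-
      data.frame(onset_s = onset, detect_s = t_cross, peak_s = t_peak,
                 amplitude = max(dF, 0), snr = snr)
    last_t <- t_cross
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(onset_s = numeric(0), detect_s = numeric(0),
               peak_s = numeric(0), amplitude = numeric(0),
               snr = numeric(0))
  attr(out, "sigma") <- sigma
  attr(out, "threshold_sigma") <- threshold_sigma
  class(out) <- c("calcium_events", "data.frame")
  out
}

#' Four-parameter transient fit
#'
#' Bounded nonlinear least squares of
#' \code{A (1 - exp(-(t - t0)/tau_up)) exp(-(t - t0)/tau_down)} (zero
#' before t0) on a window around the event peak. All parameters are
#' positive; tau_up and tau_down are constrained to upper limits of 2 and
#' 5 s. The trace should be pre-filtered with a tau = 5 ms EWMA for onset
#' estimation. A local baseline offset is co-estimated as an unbounded
#' nuisance parameter so that slow rises are not mistaken for baseline.
#'
#' @param x trace (ideally EWMA tau = 5 ms filtered).
#' @param fs sampling rate, Hz.
#' @param t_peak peak-time initial guess t1, seconds.
#' @param window fit window relative to t_peak, c(before, after) in
#'   seconds (clipped to the trace).
#' @return list of class \code{transient_fit}: \code{A}, \code{t0},
#'   \code{tau_up}, \code{tau_down}, \code{rss}, \code{converged}. A fit
#'   that fails to converge is flagged with \code{rss = Inf}.
#' @export
fit_transient <- function(x, fs, t_peak, window = c(0.5, 3)) {
  i0 <- max(1L, 1L + floor((t_peak - window[1L]) * fs))
  i1 <- min(length(x), 1L + ceiling((t_peak + window[2L]) * fs))
  tt <- (seq(i0, i1) - 1L) / fs
  yy <- x[i0:i1]
  b0 <- stats::quantile(yy, 0.05, names = FALSE)
  ymax <- max(yy) - b0
  if (ymax <= 0) {
    return(structure(list(A = NA_real_, t0 = NA_real_, tau_up = NA_real_,
                          tau_down = NA_real_, rss = Inf, converged = FALSE),
                     class = "transient_fit"))
  }
  model <- function(p, t) {
    dt <- t - p[2L]
    p[5L] + ifelse(dt >= 0,
                   p[1L] * (1 - exp(-dt / p[3L])) * exp(-dt / p[4L]), 0)
  }
  lower <- c(A = 1e-9, t0 = tt[1L], tau_up = 1e-4, tau_down = 1e-3,
             b = -Inf)
  upper <- c(A = Inf, t0 = t_peak, tau_up = 2, tau_down = 5, b = Inf)
  starts <- expand.grid(tau_up = c(0.01, 0.05, 0.2, 0.8),
                        tau_down = c(0.1, 0.5, 2, 4.5))
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    tu <- starts$tau_up[si]; td <- starts$tau_down[si]
    p0 <- c(A = ymax / ((td / (tu + td)) * (tu / (tu + td))^(tu / td)),
            t0 = max(tt[1L], min(t_peak - tu * log1p(td / tu), t_peak)),
            tau_up = tu, tau_down = td, b = b0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper,
        fn = function(p) yy - model(p, tt),
        control = minpack.lm::nls.lm.control(maxiter = 300,
                                             ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss)
    }
    if (rss <= 1e-16 * length(yy) * max(1, ymax^2)) break
  }
  if (is.null(best)) {
    return(structure(list(A = NA_real_, t0 = NA_real_, tau_up = NA_real_,
                          tau_down = NA_real_, rss = Inf, converged = FALSE),
                     class = "transient_fit"))
  }
  p <- best$par
  structure(list(A = unname(p[1L]), t0 = unname(p[2L]),
                 tau_up = unname(p[3L]), tau_down = unname(p[4L]),
                 baseline = unname(p[5L]),
                 rss = best$rss, converged = TRUE),
            class = "transient_fit")
}

#' Event signal-to-noise ratio
#'
#' SNR = dF / sd(baseline), where dF is the peak fluorescence minus the
#' mean over an event-free baseline window.
#'
#' @param x trace.
#' @param fs sampling rate, Hz.
#' @param t_peak event peak time, s.
#' @param baseline_window c(start, end) of an event-free window, s.
#' @return SNR (dimensionless).
#' @export
event_snr <- function(x, fs, t_peak, baseline_window) {
  i0 <- 1L + floor(baseline_window[1L] * fs)
  i1 <- floor(baseline_window[2L] * fs)
  if (i0 < 1L || i1 > length(x) || i1 <= i0) stop("empty baseline window")
  base <- x[i0:i1]
  pk <- x[1L + round(t_peak * fs)]
  (pk - mean(base)) / stats::sd(base)
}

#' Match calcium events to electrophysiological events
#'
#' Greedy one-to-one nearest-neighbour matching within a +/- 100 ms
#' window: candidate pairs are sorted by absolute time difference and
#' assigned in order, each event used at most once. Detection accuracy is
#' the fraction of electrophysiological events associated with a detected
#' calcium transient.
#'
#' @param calcium_times calcium event times (onsets or peaks), s, sorted.
#' @param ephys_times ground-truth event times (first AP of each event),
#'   s, sorted.
#' @param window matching half-window, s (default 0.1).
#' @return list of class \code{match_result}: \code{matched} (logical per
#'   ephys event), \code{detection_accuracy}, \code{delays_ms}
#'   (calcium - ephys per matched pair), \code{false_positives},
#'   \code{pairs} (matrix of matched index pairs).
#' @export
match_events <- function(calcium_times, ephys_times, window = 0.1) {
  nc <- length(calcium_times); ne <- length(ephys_times)
  if (ne == 0L) stop("no electrophysiological events to match")
  if (nc && is.unsorted(calcium_times)) stop("`calcium_times` must be sorted")
  if (is.unsorted(ephys_times)) stop("`ephys_times` must be sorted")
  pairs <- NULL
  if (nc) {
    dd <- abs(outer(calcium_times, ephys_times, "-"))
    cand <- which(dd <= window, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dd[cand]), , drop = FALSE]
      used_c <- logical(nc); used_e <- logical(ne)
      keep <- matrix(integer(0), ncol = 2L)
      for (k in seq_len(nrow(cand))) {
        ci <- cand[k, 1L]; ei <- cand[k, 2L]
        if (!used_c[ci] && !used_e[ei]) {
          keep <- rbind(keep, c(ci, ei))
          used_c[ci] <- TRUE; used_e[ei] <- TRUE
        }
      }
      pairs <- keep
    }
  }
  matched <- logical(ne)
  delays <- numeric(0)
  if (!is.null(pairs) && nrow(pairs)) {
    matched[pairs[, 2L]] <- TRUE
    delays <- (calcium_times[pairs[, 1L]] - ephys_times[pairs[, 2L]]) * 1000
  }
  structure(list(matched = matched,
                 detection_accuracy = mean(matched),
                 delays_ms = delays,
                 false_positives = nc - sum(matched),
                 pairs = pairs),
            class = "match_result")
}

#' Classify a spike train into bursts and single APs
#'
#' A burst is a maximal run of spikes with consecutive inter-spike
#' intervals shorter than 100 ms; a spike not preceded or followed by
#' another within 100 ms is a single AP. The maximal burst-event rate
#' under this definition is <= 10 Hz.
#'
#' @param train a \code{spike_train} (or sorted numeric times).
#' @param isi_max burst ISI criterion, s (default 0.1).
#' @return data.frame with columns \code{onset_s} (first spike of the
#'   event) and \code{n_aps}.
#' @export
classify_bursts <- function(train, isi_max = 0.1) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be sorted")
  n <- length(times)
  if (n == 0L) return(data.frame(onset_s = numeric(0), n_aps = integer(0)))
  grp <- cumsum(c(TRUE, diff(times) >= isi_max))
  data.frame(onset_s = tapply(times, grp, min),
             n_aps = as.integer(tapply(times, grp, length)),
             row.names = NULL)
}

#' Onset precision statistics
#'
#' Mean and sd of the calcium-onset delays relative to the first AP of
#' each matched electrophysiological event.
#'
#' @param match a \code{match_result}.
#' @return list with \code{mean_ms}, \code{sd_ms}, \code{n}.
#' @export
onset_precision <- function(match) {
  if (!inherits(match, "match_result")) stop("expected a match_result")
  d <- match$delays_ms
  if (!length(d)) stop("no matched pairs")
  list(mean_ms = mean(d), sd_ms = if (length(d) > 1L) stats::sd(d) else 0,
       n = length(d))
}
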