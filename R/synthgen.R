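#' Synthetic spike-train generation
#'
#' Generates a ground-truth spike train containing Poisson-placed single
#' action potentials and Poisson-placed bursts. A burst is a group of
#' spikes with consecutive inter-spike intervals shorter than 100 ms;
#' single APs are separated by at least 100 ms from any other spike.
#' Events are placed with the uniform-order-statistics construction with
#' mandatory inter-event gaps, which preserves the Poisson event counts
#' exactly while enforcing the 100 ms hard-core separation.
#'
#' @param duration recording length in seconds.
#' @param single_ap_rate rate of isolated single APs, events/s.
#' @param burst_rate rate of burst events, events/s.
#' @param burst_size_probs probability vector over burst sizes 1..4
#'   (must sum to 1).
#' @param intra_burst_isi inter-spike interval inside a burst, seconds
#'   (must be < 0.1 s).
#' @param seed integer seed; every stochastic generator takes one.
#'
#' @return An object of class \code{spike_train}: list with \code{times}
#'   (strictly increasing, in \code{[0, duration)}) and \code{duration}.
#' @export
generate_spike_train <- function(duration,
                                 single_ap_rate = 0.03,
                                 burst_rate = 0.008,
                                 burst_size_probs = c(0, 0.4, 0.35, 0.25),
                                 intra_burst_isi = 0.02,
                                 seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  if (single_ap_rate < 0 || burst_rate < 0) stop("rates must be >= 0")
  if (length(burst_size_probs) != 4L || any(burst_size_probs < 0) ||
      abs(sum(burst_size_probs) - 1) > 1e-8) {
    stop("`burst_size_probs` must be 4 non-negative probabilities summing to 1")
  }
  if (intra_burst_isi <= 0 || intra_burst_isi >= 0.1) {
    stop("`intra_burst_isi` must be in (0, 0.1) s")
  }
  set.seed(seed)
  gap <- 0.1005  # hard-core separation between events, > the 100 ms burst rule

  n_single <- stats::rpois(1L, single_ap_rate * duration)
  n_burst  <- stats::rpois(1L, burst_rate * duration)
  m <- n_single + n_burst
  if (m == 0L) return(spike_train(numeric(0), duration))

  sizes <- c(rep(1L, n_single),
             if (n_burst > 0L)
               sample.int(4L, n_burst, replace = TRUE, prob = burst_size_probs))
  sizes <- sizes[sample.int(m)]          # random interleaving of event types
  lengths <- (sizes - 1L) * intra_burst_isi
  slack <- duration - sum(lengths) - (m - 1L) * gap - gap
  if (slack <= 0) {
    stop("event rates too high for the 100 ms separation at this duration")
  }
  starts <- sort(stats::runif(m, 0, slack)) +
    c(0, cumsum(lengths[-m] + gap))
  times <- unlist(lapply(seq_len(m), function(j) {
    starts[j] + intra_burst_isi * seq(0L, sizes[j] - 1L)
  }))
  spike_train(times, duration)
}

#' Spike train constructor
#'
#' @param times spike times in seconds, strictly increasing, in
#'   \code{[0, duration)}.
#' @param duration recording length in seconds.
#' @return A \code{spike_train} object.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  if (length(times) && (min(times) < 0 || max(times) >= duration)) {
    stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s\n",
              length(x$times), x$duration))
  invisible(x)
}

#' Calcium transient kernel
#'
#' Four-parameter fluorescence response to a single action potential:
#' \deqn{k(t) = A (1 - e^{-(t - t_0)/\tau_{up}}) e^{-(t - t_0)/\tau_{down}}}
#' for \eqn{t \ge t_0}, zero before. Defaults emulate a fast GCaMP6-like
#' indicator (about 19% dF/F per AP, 50 ms rise, 600 ms decay, 5 ms onset
#' latency).
#'
#' @param amplitude_per_ap amplitude scale A, dF/F units per AP.
#' @param tau_up rise time constant, s (must be <= 2 s).
#' @param tau_down decay time constant, s (must be <= 5 s).
#' @param onset_delay latency between the AP and the fluorescence onset
#'   \eqn{t_0}, seconds.
#' @return A \code{transient_kernel} object.
#' @export
transient_kernel <- function(amplitude_per_ap = 0.19,
                             tau_up = 0.05,
                             tau_down = 0.6,
                             onset_delay = 0.005) {
  if (amplitude_per_ap < 0) stop("`amplitude_per_ap` must be >= 0")
  if (tau_up <= 0 || tau_up > 2) stop("`tau_up` must be in (0, 2] s")
  if (tau_down <= 0 || tau_down > 5) stop("`tau_down` must be in (0, 5] s")
  if (onset_delay < 0) stop("`onset_delay` must be >= 0")
  structure(list(amplitude_per_ap = amplitude_per_ap, tau_up = tau_up,
                 tau_down = tau_down, onset_delay = onset_delay),
            class = "transient_kernel")
}

#' Evaluate a transient kernel
#'
#' @param kernel a \code{transient_kernel}.
#' @param t times in seconds (vector); the kernel onset sits at
#'   \code{onset_delay}.
#' @return kernel values, zero for \code{t < onset_delay}.
#' @export
kernel_eval <- function(kernel, t) {
  tt <- t - kernel$onset_delay
  out <- numeric(length(t))
  pos <- tt >= 0
  out[pos] <- kernel$amplitude_per_ap *
    (1 - exp(-tt[pos] / kernel$tau_up)) * exp(-tt[pos] / kernel$tau_down)
  out
}

#' Spike train to fluorescence trace
#'
#' Linear superposition of one transient kernel per spike (no
#' saturation), sampled at \code{fs}.
#'
#' @param train a \code{spike_train}.
#' @param kernel a \code{transient_kernel}.
#' @param fs sampling rate, Hz.
#' @return numeric vector of length \code{round(duration * fs)}, in dF/F
#'   units; identically zero for an empty train.
#' @export
spikes_to_fluorescence <- function(train, kernel, fs) {
  if (!inherits(train, "spike_train")) stop("`train` must be a spike_train")
  if (fs <= 0) stop("`fs` must be > 0")
  n <- round(train$duration * fs)
  trace <- numeric(n)
  if (!length(train$times)) return(trace)
  tgrid <- (seq_len(n) - 1L) / fs
  for (s in train$times) {
    i0 <- max(1L, 1L + floor((s + kernel$onset_delay) * fs))
    if (i0 > n) next
    idx <- i0:n
    trace[idx] <- trace[idx] + kernel_eval(kernel, tgrid[idx] - s)
  }
  trace
}

#' Raw fluorescence from a normalized trace
#'
#' Emulates camera digits:
#' \code{F(t) = f0_level * (1 + dff(t)) + N(0, noise_sd) + drift(t)}.
#'
#' @param trace dF/F trace (numeric vector).
#' @param fs sampling rate, Hz.
#' @param noise_sd Gaussian noise sd, digits (>= 0).
#' @param f0_level baseline fluorescence, digits (> 0).
#' @param drift additive drift in digits: a function of time (s), a
#'   vector matching \code{trace}, or a scalar slope in digits/s.
#' @param seed integer seed for the noise draw.
#' @return raw fluorescence vector, digits.
#' @export
add_noise_and_baseline <- function(trace, fs, noise_sd, f0_level,
                                   drift = 0, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (f0_level <= 0) stop("`f0_level` must be > 0")
  n <- length(trace)
  tgrid <- (seq_len(n) - 1L) / fs
  d <- if (is.function(drift)) drift(tgrid)
       else if (length(drift) == n) drift
       else drift * tgrid
  set.seed(seed)
  f0_level * (1 + trace) + stats::rnorm(n, 0, noise_sd) + d
}

#' Synthetic neuronal population
#'
#' Generates a population of calcium traces with controllable synchrony.
#' Shared network events occur at \code{network_event_rate}; each cell
#' participates with probability \code{participation_prob} and a per-cell
#' Gaussian onset jitter, emulating network events in which each cell
#' shows a distinct timing of initiation. On top, each cell fires
#' independent events at \code{independent_rate}. Traces are returned in
#' dF/F units with additive Gaussian noise.
#'
#' @param n_cells number of cells.
#' @param duration recording length, s.
#' @param cell_positions n x 2 matrix of micrometre coordinates; defaults
#'   to a seeded uniform draw in a 200 x 200 um field of view (pairwise
#'   distinct).
#' @param network_event_rate shared event rate, events/s.
#' @param participation_prob per-cell recruitment probability in [0, 1].
#' @param onset_jitter_sd per-cell onset jitter sd, seconds.
#' @param independent_rate per-cell independent event rate, events/s.
#' @param noise_sd additive Gaussian noise sd, dF/F units.
#' @param kernel a \code{transient_kernel}.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return list with \code{traces} (a dF/F \code{trace_set}),
#'   \code{spike_trains} (list of \code{spike_train} ground truth),
#'   \code{network_events} (shared event times, s) and
#'   \code{cell_positions}.
#' @export
generate_population <- function(n_cells, duration,
                                cell_positions = NULL,
                                network_event_rate = 0.04,
                                participation_prob = 0.8,
                                onset_jitter_sd = 0.01,
                                independent_rate = 0.04,
                                noise_sd = 0.05,
                                kernel = transient_kernel(),
                                fs = 1000,
                                seed = 1L) {
  if (participation_prob < 0 || participation_prob > 1) {
    stop("`participation_prob` must be in [0, 1]")
  }
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  set.seed(seed)
  if (is.null(cell_positions)) {
    repeat {
      cell_positions <- cbind(stats::runif(n_cells, 0, 200),
                              stats::runif(n_cells, 0, 200))
      if (n_cells < 2 || min(stats::dist(cell_positions)) > 0) break
    }
  }
  if (nrow(cell_positions) != n_cells) {
    stop("`cell_positions` must have `n_cells` rows")
  }
  if (n_cells > 1 && min(stats::dist(cell_positions)) == 0) {
    stop("`cell_positions` must be pairwise distinct")
  }

  n_net <- stats::rpois(1L, network_event_rate * duration)
  network_events <- sort(stats::runif(n_net, 0, duration))

  n_samp <- round(duration * fs)
  traces <- matrix(0, n_cells, n_samp)
  trains <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    t_net <- network_events[stats::runif(n_net) < participation_prob]
    if (length(t_net) && onset_jitter_sd > 0) {
      t_net <- t_net + stats::rnorm(length(t_net), 0, onset_jitter_sd)
    }
    n_ind <- stats::rpois(1L, independent_rate * duration)
    t_all <- sort(c(t_net, stats::runif(n_ind, 0, duration)))
    t_all <- unique(t_all[t_all >= 0 & t_all < duration])
    trains[[i]] <- spike_train(t_all, duration)
    traces[i, ] <- spikes_to_fluorescence(trains[[i]], kernel, fs)
    if (noise_sd > 0) {
      traces[i, ] <- traces[i, ] + stats::rnorm(n_samp, 0, noise_sd)
    }
  }
  list(traces = trace_set(traces, fs, normalization = "dff0"),
       spike_trains = trains,
       network_events = network_events,
       cell_positions = cell_positions)
}

#' Apply an optical crosstalk matrix
#'
#' Mixes traces across cells: \code{mixed_i = sum_j C[j, i] * trace_j},
#' where \code{C[j, i]} is the fraction of cell j's signal appearing at
#' cell i (the contamination ratio C = Ic/Ia measured between a pair of
#' illumination sites). The diagonal (self-coefficient) must be 1.
#'
#' @param ts a \code{trace_set}.
#' @param C n x n mixing matrix, diagonal 1, off-diagonal in [0, 1].
#' @return a mixed \code{trace_set} with the same metadata.
#' @export
apply_crosstalk <- function(ts, C) {
  .assert_trace_set(ts)
  n <- n_cells(ts)
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("`C` must be square")
  if (nrow(C) != n) stop("crosstalk matrix dimension must match n_cells")
  if (any(abs(diag(C) - 1) > 1e-12)) stop("diagonal of `C` must be 1")
  off <- C[row(C) != col(C)]
  if (any(off < 0 | off > 1)) stop("off-diagonal entries must be in [0, 1]")
  out <- ts
  out$traces <- t(C) %*% ts$traces
  rownames(out$traces) <- ts$labels
  out
}

#' Inject a square light-stimulus artifact
#'
#' Adds a square pulse of the given amplitude during each stimulation
#' epoch, emulating the stimulus artifact seen during single-photon
#' optogenetic illumination (e.g. a 1 s stimulus).
#'
#' @param trace numeric trace (or \code{trace_set}; applied to all rows).
#' @param fs sampling rate, Hz (ignored for a \code{trace_set}).
#' @param epochs two-column matrix/data.frame (onset_s, duration_s);
#'   epochs must be non-overlapping and inside the recording.
#' @param amplitude artifact amplitude in trace units.
#' @return trace (or \code{trace_set}) with artifacts added.
#' @export
inject_light_artifact <- function(trace, fs, epochs, amplitude) {
  epochs <- as.matrix(epochs)
  if (ncol(epochs) != 2L) stop("`epochs` must have columns (onset, duration)")
  if (any(epochs[, 2L] <= 0)) stop("epoch durations must be > 0")
  o <- order(epochs[, 1L])
  ep <- epochs[o, , drop = FALSE]
  if (nrow(ep) > 1L &&
      any(ep[-1L, 1L] < ep[-nrow(ep), 1L] + ep[-nrow(ep), 2L])) {
    stop("epochs must be non-overlapping")
  }
  if (inherits(trace, "trace_set")) {
    out <- trace
    out$traces <- t(apply(trace$traces, 1L, inject_light_artifact,
                          fs = trace$fs, epochs = epochs,
                          amplitude = amplitude))
    rownames(out$traces) <- trace$labels
    return(out)
  }
  n <- length(trace)
  dur <- n / fs
  if (any(ep[, 1L] < 0) || any(ep[, 1L] + ep[, 2L] > dur)) {
    stop("epochs must lie inside the recording")
  }
  for (k in seq_len(nrow(ep))) {
    i0 <- 1L + floor(ep[k, 1L] * fs)
    i1 <- min(n, ceiling((ep[k, 1L] + ep[k, 2L]) * fs))
    trace[i0:i1] <- trace[i0:i1] + amplitude
  }
  trace
}
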