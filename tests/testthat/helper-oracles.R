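# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, O(T*W)) so they share no code with
# the implementations they check.

naive_ewma <- function(x, tau, fs) {
  alpha <- 1 - exp(-1 / (fs * tau))
  y <- numeric(length(x))
  y[1] <- x[1]
  for (t in seq_along(x)[-1]) y[t] <- alpha * x[t] + (1 - alpha) * y[t - 1]
  y
}

naive_moving_average <- function(x, window, fs) {
  w <- max(1L, round(window * fs))
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - left):min(n, i + right)])
  }, numeric(1))
}

naive_f0 <- function(x, fs, ma_window = 0.75, min_halfwindow = 1.5) {
  sm <- naive_moving_average(x, ma_window, fs)
  h <- round(min_halfwindow * fs)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    min(sm[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# exhaustive one-to-one assignment maximizing the number of matches and,
# among those, minimizing the summed |delay|; feasible for tiny inputs
brute_force_match <- function(ca, ep, window = 0.1) {
  nc <- length(ca); ne <- length(ep)
  best <- list(n = -1L, cost = Inf, matched = logical(ne))
  assign_rec <- function(ei, used_c, matched, cost) {
    if (ei > ne) {
      n <- sum(matched)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, matched = matched)
      }
      return(invisible())
    }
    assign_rec(ei + 1L, used_c, matched, cost)  # leave ephys event unmatched
    for (ci in seq_len(nc)) {
      if (!used_c[ci] && abs(ca[ci] - ep[ei]) <= window) {
        used_c2 <- used_c; used_c2[ci] <- TRUE
        matched2 <- matched; matched2[ei] <- TRUE
        assign_rec(ei + 1L, used_c2, matched2, cost + abs(ca[ci] - ep[ei]))
      }
    }
  }
  assign_rec(1L, logical(nc), logical(ne), 0)
  best
}

# dense grid search for the transient onset t0: A is profiled out
# analytically (linear parameter), tau_up/tau_down on a coarse grid
grid_search_t0 <- function(tt, yy, t0_grid,
                           tau_up_grid = c(0.02, 0.05, 0.1),
                           tau_down_grid = c(0.3, 0.5, 0.8)) {
  best_rss <- Inf; best_t0 <- NA_real_
  for (t0 in t0_grid) for (tu in tau_up_grid) for (td in tau_down_grid) {
    dt <- tt - t0
    k <- ifelse(dt >= 0, (1 - exp(-dt / tu)) * exp(-dt / td), 0)
    denom <- sum(k^2)
    if (denom == 0) next
    a <- sum(yy * k) / denom
    rss <- sum((yy - a * k)^2)
    if (rss < best_rss) { best_rss <- rss; best_t0 <- t0 }
  }
  best_t0
}

# single-spike synthetic trace with Gaussian noise, for detection tests
synth_trace <- function(duration, fs, spike_times, noise_sd, seed,
                        kernel = transient_kernel()) {
  tr <- spike_train(spike_times, duration)
  x <- spikes_to_fluorescence(tr, kernel, fs)
  set.seed(seed)
  x + rnorm(length(x), 0, noise_sd)
}
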