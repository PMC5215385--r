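#' ROI geometry: 4 signal pixels and a 20-pixel background ring
#'
#' For an illumination site at (possibly fractional) pixel coordinates,
#' the signal is measured over the 4 pixels closest to the site and the
#' local background over an outer ring of twenty pixels. The ring is
#' formed by the 20 pixels whose centre distance is closest to 2.5 px
#' from the site, excluding the signal pixels; ties are broken
#' deterministically by (angle, index). Coordinates are 0-based
#' (row, col) with pixel centres at integers.
#'
#' @param site length-2 numeric (row, col), 0-based.
#' @param dim_hw image dimensions c(height, width).
#' @return list with integer matrices \code{signal_pixels} (4 x 2) and
#'   \code{ring_pixels} (20 x 2), 0-based (row, col).
#' @export
roi_geometry <- function(site, dim_hw) {
  site <- as.numeric(site)
  h <- dim_hw[1L]; w <- dim_hw[2L]
  r0 <- floor(site[1L]); c0 <- floor(site[2L])
  # candidate window comfortably covering the ring radius
  rows <- (r0 - 5L):(r0 + 6L)
  cols <- (c0 - 5L):(c0 + 6L)
  if (min(rows) < 0L || min(cols) < 0L || max(rows) >= h || max(cols) >= w) {
    stop("site too close to the image border for the 20-pixel ring")
  }
  cand <- expand.grid(row = rows, col = cols)
  dr <- cand$row - site[1L]; dc <- cand$col - site[2L]
  d <- sqrt(dr^2 + dc^2)
  ang <- atan2(dc, dr) %% (2 * pi)
  ord <- order(d, ang, seq_along(d))
  sig_i <- ord[1:4]
  rest <- setdiff(seq_along(d), sig_i)
  ring_ord <- rest[order(abs(d[rest] - 2.5), ang[rest], rest)]
  ring_i <- ring_ord[1:20]
  list(signal_pixels = cbind(row = cand$row[sig_i], col = cand$col[sig_i]),
       ring_pixels = cbind(row = cand$row[ring_i], col = cand$col[ring_i]))
}

#' Extract ROI traces from an image stack
#'
#' Per frame, the signal trace is the mean over the 4 pixels closest to
#' each illumination site and the background trace the mean over the
#' 20-pixel outer ring (see \code{\link{roi_geometry}}). Intensities are
#' in camera digits (dgt).
#'
#' @param stack numeric array T x H x W, non-negative.
#' @param sites m x 2 matrix of site coordinates, 0-based (row, col).
#' @param fs frame rate, Hz.
#' @param labels optional cell labels.
#' @return list with \code{signal} and \code{background}, both raw-digit
#'   \code{trace_set}s, plus \code{geometries}.
#' @export
extract_traces <- function(stack, sites, fs, labels = NULL) {
  if (length(dim(stack)) != 3L) stop("`stack` must be a T x H x W array")
  if (any(stack < 0)) stop("stack intensities must be non-negative")
  sites <- matrix(as.numeric(sites), ncol = 2L)
  nt <- dim(stack)[1L]
  m <- nrow(sites)
  sig <- matrix(0, m, nt); bg <- matrix(0, m, nt)
  geoms <- vector("list", m)
  flat <- matrix(stack, nrow = nt)  # T x (H*W), column-major over (row, col)
  h <- dim(stack)[2L]
  for (i in seq_len(m)) {
    g <- roi_geometry(sites[i, ], dim(stack)[2:3])
    geoms[[i]] <- g
    sidx <- g$signal_pixels[, 1L] + 1L + h * g$signal_pixels[, 2L]
    ridx <- g$ring_pixels[, 1L] + 1L + h * g$ring_pixels[, 2L]
    sig[i, ] <- rowMeans(flat[, sidx, drop = FALSE])
    bg[i, ]  <- rowMeans(flat[, ridx, drop = FALSE])
  }
  list(signal = trace_set(sig, fs, labels, "raw_dgt"),
       background = trace_set(bg, fs, labels, "raw_dgt"),
       geometries = geoms)
}

#' Centred moving average with truncated edges
#'
#' Boxcar smoother; at the boundaries the window shrinks to the available
#' samples (no padding is fabricated).
#'
#' @param x numeric trace.
#' @param window window length in seconds.
#' @param fs sampling rate, Hz.
#' @return smoothed trace, same length.
#' @export
moving_average <- function(x, window, fs) {
  w <- max(1L, round(window * fs))
  if (w == 1L) return(x)
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + right, n)
  lo <- pmax(seq_len(n) - left, 1L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# running minimum over the window [i - h, i + h] (van Herk two-pass,
# +Inf padding implements truncated edges)
.running_min <- function(x, h) {
  if (h == 0L) return(x)
  n <- length(x)
  w <- 2L * h + 1L
  nblk <- ceiling((n + 2L * h) / w)
  padded <- c(rep(Inf, h), x, rep(Inf, nblk * w - n - h))
  m <- matrix(padded, nrow = w)
  pref <- apply(m, 2L, cummin)
  suff <- apply(m[w:1, , drop = FALSE], 2L, cummin)[w:1, , drop = FALSE]
  i <- seq_len(n)
  pmin(as.vector(suff)[i], as.vector(pref)[i + 2L * h])
}

#' Running-minimum fluorescence baseline F0(t)
#'
#' The baseline is computed by smoothing the trace with a 0.75 s centred
#' moving average and then taking the minimum over a running window of
#' +/- 1.5 s. Edge windows are truncated.
#'
#' @param x raw fluorescence trace.
#' @param fs sampling rate, Hz.
#' @param ma_window smoothing window, s (default 0.75).
#' @param min_halfwindow running-minimum half window, s (default 1.5).
#' @return baseline trace F0(t), same length as \code{x}.
#' @export
compute_f0 <- function(x, fs, ma_window = 0.75, min_halfwindow = 1.5) {
  if (length(x) < 3 * fs) stop("trace must be at least 3 s long")
  sm <- moving_average(x, ma_window, fs)
  .running_min(sm, round(min_halfwindow * fs))
}

#' Normalize fluorescence traces
#'
#' \code{dff0}: \code{(F(t) - F0(t)) / F0(t)} with the running-minimum
#' baseline of \code{\link{compute_f0}}. \code{dfbg}:
#' \code{(F(t) - bg(t)) / bg(t)} with the 20-pixel ring background trace.
#'
#' @param signal a raw-digit \code{trace_set}.
#' @param mode "dff0" or "dfbg".
#' @param background a \code{trace_set} of ring backgrounds (dfbg only).
#' @param ... passed to \code{\link{compute_f0}}.
#' @return normalized \code{trace_set}; the denominator traces are
#'   attached as element \code{denominator} for lossless inversion.
#' @export
normalize_traces <- function(signal, mode = c("dff0", "dfbg"),
                             background = NULL, ...) {
  .assert_trace_set(signal)
  mode <- match.arg(mode)
  X <- signal$traces
  if (mode == "dff0") {
    denom <- t(apply(X, 1L, compute_f0, fs = signal$fs, ...))
  } else {
    if (is.null(background)) stop("`dfbg` requires a background trace_set")
    .assert_trace_set(background)
    if (!all(dim(background$traces) == dim(X))) {
      stop("background dimensions must match the signal")
    }
    denom <- background$traces
  }
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive denominator at %d sample(s), first indices: %s",
                 length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
  }
  out <- signal
  out$traces <- (X - denom) / denom
  rownames(out$traces) <- signal$labels
  out$normalization <- mode
  out$denominator <- denom
  out
}

#' Undo a normalization
#'
#' Reconstructs the raw trace \code{F = denom * (1 + dff)} from a
#' normalized \code{trace_set} carrying its denominator.
#'
#' @param ts normalized \code{trace_set} produced by
#'   \code{\link{normalize_traces}}.
#' @return raw-digit \code{trace_set}.
#' @export
denormalize_traces <- function(ts) {
  .assert_trace_set(ts)
  if (is.null(ts$denominator)) stop("trace_set carries no denominator")
  out <- ts
  out$traces <- ts$denominator * (1 + ts$traces)
  rownames(out$traces) <- ts$labels
  out$normalization <- "raw_dgt"
  out$denominator <- NULL
  out
}

#' Relative baseline change
#'
#' \code{(B_f - B_0) / B_0}, where B_0 and B_f are mean raw fluorescence
#' over an initial and a final activity-free window (about 0.5 s each).
#'
#' @param x raw fluorescence trace.
#' @param fs sampling rate, Hz.
#' @param initial_window c(start, end) in seconds.
#' @param final_window c(start, end) in seconds.
#' @return relative baseline change (dimensionless).
#' @export
baseline_change <- function(x, fs, initial_window, final_window) {
  n <- length(x)
  win_idx <- function(w) {
    i0 <- 1L + floor(w[1L] * fs); i1 <- floor(w[2L] * fs)
    if (i0 < 1L || i1 > n || i1 < i0) stop("window outside trace")
    i0:i1
  }
  b0 <- mean(x[win_idx(initial_window)])
  bf <- mean(x[win_idx(final_window)])
  (bf - b0) / b0
}

#' Exponentially weighted moving average
#'
#' First-order low-pass \code{y_t = alpha x_t + (1 - alpha) y_{t-1}} with
#' \code{alpha = 1 - exp(-1 / (fs * tau))}, so \code{tau} is the true
#' exponential decay constant of the impulse response; \code{y_1 = x_1}.
#'
#' @param x numeric trace.
#' @param tau decay time constant, s.
#' @param fs sampling rate, Hz.
#' @return filtered trace, same length.
#' @export
ewma <- function(x, tau, fs) {
  if (tau <= 0) stop("`tau` must be > 0")
  alpha <- 1 - exp(-1 / (fs * tau))
  as.numeric(stats::filter(alpha * x, 1 - alpha,
                           method = "recursive", init = x[1L]))
}

#' Average integral of a normalized trace
#'
#' Trapezoidal time-integral of the dF/F trace divided by the recording
#' duration; a constant trace of value c integrates to c.
#'
#' @param x normalized trace.
#' @param fs sampling rate, Hz (only the sample count matters for the
#'   time-averaged value).
#' @return average integral (dF/F units).
#' @export
trace_integral <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stop("trace too short to integrate")
  (sum(x) - (x[1L] + x[n]) / 2) / (n - 1L)
}
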