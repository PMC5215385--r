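#' Pairwise Pearson correlation of calcium traces
#'
#' Traces are first filtered with an EWMA (decay time tau, default
#' 15 ms), then the Pearson correlation is computed for every neuronal
#' pair over the full duration. A constant trace has undefined
#' correlation; its pairs are reported as NA with a warning.
#'
#' @param ts a \code{trace_set} with >= 2 cells.
#' @param tau EWMA decay constant, s; \code{NULL} skips filtering.
#' @return symmetric n x n correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(ts, tau = 0.015) {
  .assert_trace_set(ts)
  if (n_cells(ts) < 2L) stop("at least 2 cells are required")
  X <- ts$traces
  if (!is.null(tau)) {
    X <- t(apply(X, 1L, ewma, tau = tau, fs = ts$fs))
  }
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant trace(s): correlations reported as NA",
                    sum(sds == 0)))
  }
  M <- suppressWarnings(stats::cor(t(X)))
  diag(M) <- 1
  M <- (M + t(M)) / 2
  dimnames(M) <- list(ts$labels, ts$labels)
  M
}

#' Average network correlation
#'
#' Mean Pearson correlation across all possible neuronal pairs (mean of
#' the upper-triangle off-diagonal entries). NA pairs (constant traces)
#' are excluded.
#'
#' @param M pairwise correlation matrix.
#' @return scalar network correlation.
#' @export
network_correlation <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("`M` must be square")
  if (nrow(M) < 2L) stop("at least 2 cells are required")
  up <- M[upper.tri(M)]
  if (all(is.na(up))) stop("no valid pairs")
  mean(up, na.rm = TRUE)
}

#' Instantaneous network correlation
#'
#' Network correlation recomputed in overlapping sliding time windows
#' (default 1 s window, 0.1 s stride) on EWMA-filtered traces.
#'
#' @param ts a \code{trace_set}.
#' @param window window length, s (default 1).
#' @param stride window stride, s (default 0.1).
#' @param tau EWMA decay constant, s.
#' @return data.frame with \code{time_s} (window centre) and \code{r}.
#' @export
instantaneous_network_correlation <- function(ts, window = 1, stride = 0.1,
                                              tau = 0.015) {
  .assert_trace_set(ts)
  if (n_cells(ts) < 2L) stop("at least 2 cells are required")
  if (window > duration(ts)) stop("window longer than the recording")
  X <- ts$traces
  if (!is.null(tau)) X <- t(apply(X, 1L, ewma, tau = tau, fs = ts$fs))
  wlen <- round(window * ts$fs)
  step <- max(1L, round(stride * ts$fs))
  starts <- seq(1L, ncol(X) - wlen + 1L, by = step)
  r <- vapply(starts, function(s) {
    M <- suppressWarnings(stats::cor(t(X[, s:(s + wlen - 1L), drop = FALSE])))
    up <- M[upper.tri(M)]
    mean(up, na.rm = TRUE)
  }, numeric(1L))
  data.frame(time_s = (starts - 1L + wlen / 2) / ts$fs, r = r)
}

#' Stimulus-epoch network correlation (light off vs light on)
#'
#' For each stimulation epoch, the network correlation is evaluated in
#' the 1 s window preceding the stimulus onset (light off) and over the
#' stimulus duration (light on).
#'
#' @param ts a \code{trace_set} with >= 2 cells.
#' @param epochs two-column matrix/data.frame (onset_s, duration_s); each
#'   onset must leave >= 1 s of pre-stimulus window.
#' @param tau EWMA decay constant, s.
#' @param pre_window pre-stimulus window length, s (default 1).
#' @return list with per-epoch data.frame (\code{off}, \code{on}) and
#'   \code{mean_off}, \code{mean_on}.
#' @export
epoch_correlation <- function(ts, epochs, tau = 0.015, pre_window = 1) {
  .assert_trace_set(ts)
  if (n_cells(ts) < 2L) stop("at least 2 cells are required")
  epochs <- as.matrix(epochs)
  if (any(epochs[, 1L] < pre_window)) {
    stop("insufficient pre-stimulus window before an epoch onset")
  }
  if (any(epochs[, 1L] + epochs[, 2L] > duration(ts))) {
    stop("epoch extends past the end of the recording")
  }
  X <- ts$traces
  if (!is.null(tau)) X <- t(apply(X, 1L, ewma, tau = tau, fs = ts$fs))
  netcor <- function(i0, i1) {
    M <- suppressWarnings(stats::cor(t(X[, i0:i1, drop = FALSE])))
    mean(M[upper.tri(M)], na.rm = TRUE)
  }
  res <- t(apply(epochs, 1L, function(e) {
    on0 <- 1L + floor(e[1L] * ts$fs)
    on1 <- min(ncol(X), floor((e[1L] + e[2L]) * ts$fs))
    off0 <- 1L + floor((e[1L] - pre_window) * ts$fs)
    c(off = netcor(off0, on0 - 1L), on = netcor(on0, on1))
  }))
  res <- as.data.frame(res)
  list(epochs = res, mean_off = mean(res$off), mean_on = mean(res$on))
}
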