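#' Fluorescence trace set
#'
#' Container for a cells x time fluorescence matrix together with its
#' sampling rate, cell labels and normalization state. This is the common
#' currency passed between the synthetic generator, the trace-processing
#' operations, event detection and the correlation statistics.
#'
#' @param traces numeric matrix, one row per cell, one column per sample.
#'   A single trace may be given as a numeric vector.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of cell labels; defaults to
#'   \code{"cell1"}, \code{"cell2"}, ...
#' @param normalization one of \code{"raw_dgt"} (camera digits),
#'   \code{"dff0"} (dF/F0 against a running-minimum baseline) or
#'   \code{"dfbg"} (dF/bg against a ring background).
#'
#' @return An object of class \code{trace_set}: a list with elements
#'   \code{traces}, \code{fs}, \code{labels}, \code{normalization}.
#' @export
trace_set <- function(traces, fs,
                      labels = NULL,
                      normalization = c("raw_dgt", "dff0", "dfbg")) {
  if (is.vector(traces) && is.numeric(traces)) {
    traces <- matrix(traces, nrow = 1L)
  }
  if (!is.matrix(traces) || !is.numeric(traces)) {
    stop("`traces` must be a numeric matrix (cells x time)")
  }
  if (!all(is.finite(traces))) stop("`traces` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  normalization <- match.arg(normalization)
  if (is.null(labels)) labels <- paste0("cell", seq_len(nrow(traces)))
  if (length(labels) != nrow(traces)) {
    stop("`labels` length must equal the number of rows of `traces`")
  }
  rownames(traces) <- labels
  structure(
    list(traces = traces, fs = fs, labels = as.character(labels),
         normalization = normalization),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cell(s) x %d samples @ %g Hz (%.3g s), %s\n",
              nrow(x$traces), ncol(x$traces), x$fs,
              ncol(x$traces) / x$fs, x$normalization))
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$traces)

#' Number of cells / duration helpers
#' @param x a \code{trace_set}.
#' @return \code{n_cells}: integer count; \code{duration}: seconds.
#' @export
n_cells <- function(x) nrow(x$traces)

#' @rdname n_cells
#' @export
duration <- function(x) ncol(x$traces) / x$fs

.assert_trace_set <- function(x) {
  if (!inherits(x, "trace_set")) stop("expected a `trace_set` object")
  invisible(x)
}
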