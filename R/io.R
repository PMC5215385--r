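#' Write a trace set to CSV
#'
#' CSV dialect: UTF-8, comma separated, a metadata block of comment lines
#' (\code{# holotrace_traceset: v1}, \code{# fs_hz: <Hz>},
#' \code{# normalization: <tag>}) followed by a header row
#' (\code{time_s}, one column per cell labelled with the cell names) and
#' one row per sample. The round trip through
#' \code{\link{read_traces}} is lossless.
#'
#' @param ts a \code{trace_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_traces <- function(ts, path) {
  .assert_trace_set(ts)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# holotrace_traceset: v1",
               sprintf("# fs_hz: %.17g", ts$fs),
               sprintf("# normalization: %s", ts$normalization)), con)
  df <- data.frame((seq_len(ncol(ts$traces)) - 1L) / ts$fs,
                   t(ts$traces), check.names = FALSE)
  names(df) <- c("time_s", ts$labels)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace set from CSV
#'
#' Parses the dialect written by \code{\link{write_traces}}; the
#' \code{fs_hz} metadata line is mandatory and NaN cells are rejected
#' with their sample indices.
#'
#' @param path CSV file.
#' @return a \code{trace_set}.
#' @export
read_traces <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- grep("^#", header, value = TRUE)
  fs_line <- grep("^# fs_hz:", meta, value = TRUE)
  if (!length(fs_line)) {
    stop("format error: missing `# fs_hz:` metadata line in ", path)
  }
  fs <- as.numeric(sub("^# fs_hz:", "", fs_line[1L]))
  if (!is.finite(fs) || fs <= 0) stop("format error: invalid fs in ", path)
  norm_line <- grep("^# normalization:", meta, value = TRUE)
  norm <- if (length(norm_line)) trimws(sub("^# normalization:", "", norm_line[1L]))
          else "raw_dgt"
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1L] != "time_s") {
    stop("format error: first column must be `time_s` in ", path)
  }
  X <- t(as.matrix(df[, -1L, drop = FALSE]))
  bad <- which(!is.finite(X))
  if (length(bad)) {
    stop(sprintf("format error: %d non-finite cell(s) in %s, first indices: %s",
                 length(bad), path, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  trace_set(X, fs, labels = names(df)[-1L], normalization = norm)
}

#' Write / read spike trains as CSV (cell_id, time_s)
#'
#' @param trains list of \code{spike_train} objects.
#' @param path CSV file.
#' @return \code{write_spike_trains}: \code{path} invisibly;
#'   \code{read_spike_trains}: a named list of \code{spike_train}s.
#' @export
write_spike_trains <- function(trains, path) {
  ids <- names(trains)
  if (is.null(ids)) ids <- paste0("cell", seq_along(trains))
  df <- do.call(rbind, lapply(seq_along(trains), function(i) {
    if (!length(trains[[i]]$times)) return(NULL)
    data.frame(cell_id = ids[i], time_s = trains[[i]]$times)
  }))
  if (is.null(df)) df <- data.frame(cell_id = character(0), time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param duration recording duration, s (spike CSVs do not carry it).
#' @export
read_spike_trains <- function(path, duration) {
  df <- utils::read.csv(path)
  lapply(split(df$time_s, df$cell_id), spike_train, duration = duration)
}

#' Write detected events to CSV
#'
#' Columns: cell_id, onset_s, peak_s, amplitude, snr.
#'
#' @param events named list of \code{calcium_events} data.frames (one per
#'   cell) or a single \code{calcium_events}.
#' @param path CSV file.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "calcium_events")) events <- list(cell1 = events)
  ids <- names(events)
  df <- do.call(rbind, lapply(seq_along(events), function(i) {
    e <- as.data.frame(events[[i]])
    if (!nrow(e)) return(NULL)
    cbind(cell_id = ids[i], e)
  }))
  if (is.null(df)) {
    df <- data.frame(cell_id = character(0), onset_s = numeric(0),
                     peak_s = numeric(0), amplitude = numeric(0),
                     snr = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the synthesis-analysis pipeline with their
#' defaults; unknown keys in a user configuration are rejected.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    population = list(n_cells = 20L, duration = 60, fs = 1000,
                      network_event_rate = 0.04, participation_prob = 0.8,
                      onset_jitter_sd = 0.01, independent_rate = 0.04,
                      noise_sd = 0.05),
    kernel = list(amplitude_per_ap = 0.19, tau_up = 0.05, tau_down = 0.6,
                  onset_delay = 0.005),
    detection = list(threshold_sigma = 5, tau_filter = 0.1,
                     deriv_ma_window = 0.1, refractory = 0.15,
                     rectify_negative = FALSE, fit_onsets = FALSE),
    correlation = list(tau = 0.015, window = 1, stride = 0.1),
    match_window = 0.1
  )
}

# deep-merge user config into defaults, rejecting unknown keys
.merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]])) {
      .merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else user[[k]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Values omitted from the file take their defaults (and the resolved
#' configuration is embedded in the pipeline report); unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return full resolved configuration list.
#' @export
read_config <- function(path) {
  .merge_config(yaml::read_yaml(path))
}

#' Run the synthesis-analysis pipeline
#'
#' Chains the synthetic population generator, per-cell event detection,
#' spike matching against the generated ground truth, and the pairwise /
#' network correlation statistics, and returns a report that embeds the
#' fully resolved configuration. The run is deterministic given the
#' configuration and seed. One log line per stage records input shapes
#' and elapsed time.
#'
#' @param config configuration list (see \code{\link{default_config}})
#'   or path to a YAML file.
#' @param out_dir optional directory; when given, traces, ground-truth
#'   spikes, events and the JSON report are written there.
#' @param quiet suppress stage logging.
#' @return report list: \code{config}, \code{events} (per cell),
#'   \code{detection_accuracy}, \code{correlation} (matrix),
#'   \code{network_correlation}, \code{n_events}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- .merge_config(config)
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[pipeline] ", fmt), ...))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    log_stage("%s done in %.2f s", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  kern <- do.call(transient_kernel, config$kernel)
  p <- config$population
  pop <- stage(sprintf("synth (%d cells x %g s @ %g Hz)",
                       p$n_cells, p$duration, p$fs), {
    generate_population(n_cells = p$n_cells, duration = p$duration,
                        network_event_rate = p$network_event_rate,
                        participation_prob = p$participation_prob,
                        onset_jitter_sd = p$onset_jitter_sd,
                        independent_rate = p$independent_rate,
                        noise_sd = p$noise_sd, kernel = kern,
                        fs = p$fs, seed = config$seed)
  })

  d <- config$detection
  events <- stage("detect", {
    lapply(seq_len(n_cells(pop$traces)), function(i) {
      detect_events(pop$traces$traces[i, ], pop$traces$fs,
                    threshold_sigma = d$threshold_sigma,
                    tau_filter = d$tau_filter,
                    deriv_ma_window = d$deriv_ma_window,
                    refractory = d$refractory,
                    rectify_negative = d$rectify_negative,
                    fit_onsets = d$fit_onsets)
    })
  })
  names(events) <- pop$traces$labels

  acc <- stage("match", {
    vapply(seq_along(events), function(i) {
      gt <- classify_bursts(pop$spike_trains[[i]])$onset_s
      if (!length(gt)) return(NA_real_)
      match_events(sort(events[[i]]$onset_s), gt,
                   window = config$match_window)$detection_accuracy
    }, numeric(1L))
  })

  co <- config$correlation
  M <- stage("correlate", pairwise_correlation(pop$traces, tau = co$tau))
  report <- list(
    config = config,
    n_events = vapply(events, nrow, integer(1L)),
    events = lapply(events, as.data.frame),
    detection_accuracy = acc,
    mean_detection_accuracy = mean(acc, na.rm = TRUE),
    correlation = M,
    network_correlation = network_correlation(M))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_traces(pop$traces, file.path(out_dir, "traces.csv"))
    write_spike_trains(pop$spike_trains, file.path(out_dir, "spikes.csv"))
    write_events(events, file.path(out_dir, "events.csv"))
    jsonlite::write_json(
      list(config = config, n_events = report$n_events,
           detection_accuracy = report$detection_accuracy,
           mean_detection_accuracy = report$mean_detection_accuracy,
           network_correlation = report$network_correlation),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("report written to %s", out_dir)
  }
  report
}

#' Export a phase mask as 16-bit TIFF
#'
#' Phase values in [0, 2 pi) are scaled over the full 16-bit range
#' (0 maps to 0, 2 pi maps to 65535), the usual format consumed by SLM
#' control software.
#'
#' @param mask phase matrix from \code{\link{wgs}}.
#' @param path output TIFF file.
#' @return \code{path}, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF export")
  }
  tiff::writeTIFF(unclass(mask) / (2 * pi), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an image stack from a (multi-page) TIFF
#'
#' @param path TIFF file.
#' @param fs frame rate, Hz (attached as an attribute).
#' @return numeric array T x H x W with attribute \code{fs}.
#' @export
read_stack_tiff <- function(path, fs) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF import")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  attr(stack, "fs") <- fs
  stack
}
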