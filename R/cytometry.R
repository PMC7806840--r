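# Event-level preprocessing: reading tabular event files, density gating on
# the scatter channels, and cell-size-conditioned median fluorescence.

#' Read an event-level sample from a CSV file
#'
#' Expects a header row and one row per event. Channel names are
#' configurable so files from different instruments map onto the canonical
#' FSC / SSC / FL1 channels. If a JSON sidecar `<path>.json` exists, its
#' `gate`, `context`, `iptg_uM` and `role` fields are attached as metadata.
#'
#' @param path CSV file path.
#' @param channels Named character vector mapping canonical channel names
#'   (`FSC`, `SSC`, `FL1`) to column names in the file.
#' @return An `event_table`.
#' @export
read_events <- function(path, channels = c(FSC = "FSC", SSC = "SSC", FL1 = "FL1")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("no events in file: ", path, call. = FALSE)
  missing <- setdiff(unname(channels[c("FSC", "SSC", "FL1")]), names(df))
  if (length(missing)) {
    stop("missing channel column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  out <- .make_event_table(df[[channels[["FSC"]]]], df[[channels[["SSC"]]]],
                           df[[channels[["FL1"]]]], role = "gate")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (field in c("role", "gate", "context_label", "iptg_uM")) {
      if (!is.null(meta[[field]])) attr(out, field) <- meta[[field]]
    }
  }
  out
}

#' Write an event table as CSV with a JSON metadata sidecar
#'
#' @param events An `event_table`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(event_id = seq_len(nrow(events)),
                   FSC = events$FSC, SSC = events$SSC, FL1 = events$FL1)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(role = attr(events, "role"), gate = attr(events, "gate"),
               context_label = attr(events, "context_label"),
               iptg_uM = attr(events, "iptg_uM"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Density gating on the scatter channels
#'
#' Bins the (FSC, SSC) plane into a 2D histogram and retains events in the
#' densest bins, greedily included until at least the requested fraction of
#' events is covered — emulating auto-gating that covers at least half of
#' all events in the scatter plot. Ties between equally dense bins are
#' broken by bin index, so gating is deterministic.
#'
#' @param events An `event_table`.
#' @param coverage Minimum fraction of events to retain, in (0, 1].
#' @param bins Histogram resolution per axis.
#' @param log_scale Bin on log-transformed scatter values.
#' @return The gated `event_table` (metadata preserved, plus a
#'   `gating_coverage` attribute).
#' @export
scatter_gate <- function(events, coverage = 0.5, bins = 64, log_scale = FALSE) {
  if (nrow(events) == 0) stop("cannot gate an empty event table", call. = FALSE)
  stopifnot(coverage > 0, coverage <= 1)
  if (coverage == 1) {
    attr(events, "gating_coverage") <- 1
    return(events)
  }
  x <- events$FSC
  y <- events$SSC
  if (log_scale) { x <- log(x); y <- log(y) }
  bin_of <- function(v) {
    if (diff(range(v)) == 0) return(rep(1L, length(v)))
    brk <- seq(min(v), max(v), length.out = bins + 1L)
    pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L), bins)
  }
  cell <- (bin_of(x) - 1L) * bins + bin_of(y)
  counts <- tabulate(cell, nbins = bins * bins)
  ord <- order(-counts, seq_along(counts))  # densest first, index breaks ties
  cum <- cumsum(counts[ord])
  n_keep_bins <- which(cum >= coverage * nrow(events))[1]
  keep_cells <- ord[seq_len(n_keep_bins)]
  keep <- cell %in% keep_cells
  out <- events[keep, , drop = FALSE]
  for (field in c("role", "gate", "context_label", "iptg_uM")) {
    attr(out, field) <- attr(events, field)
  }
  class(out) <- c("event_table", "data.frame")
  attr(out, "gating_coverage") <- mean(keep)
  out
}

#' Common scatter reference across samples
#'
#' Pools forward scatter over all samples and returns the mode of its
#' histogram (midpoint of the most populated bin; first bin on ties).
#' Conditioning every sample's median on a window around a common scatter
#' value removes between-sample cell-size effects on fluorescence.
#'
#' @param samples A list of `event_table`s (or a single one).
#' @param bins Histogram bin count.
#' @return Scatter reference value (a.u.).
#' @export
choose_scatter_reference <- function(samples, bins = 100) {
  if (inherits(samples, "event_table")) samples <- list(samples)
  if (length(samples) == 0) stop("no samples to pool", call. = FALSE)
  pooled <- unlist(lapply(samples, function(s) s$FSC), use.names = FALSE)
  if (length(pooled) == 0) stop("no events in pooled samples", call. = FALSE)
  if (diff(range(pooled)) == 0) return(pooled[1])
  brk <- seq(min(pooled), max(pooled), length.out = bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(pooled, brk, rightmost.closed = TRUE),
                               1L), bins), nbins = bins)
  i <- which.max(counts)
  (brk[i] + brk[i + 1L]) / 2
}

#' Median fluorescence conditioned on cell size
#'
#' Takes the fluorescence distribution at (a window around) a single
#' forward-scatter value and reports its median. With an infinite window
#' this degenerates to the plain sample median.
#'
#' @param events An `event_table`.
#' @param scatter_reference Center of the scatter window (a.u.). Ignored
#'   when `window_halfwidth` is infinite.
#' @param window_halfwidth Half-width of the FSC window (a.u.); `Inf`
#'   disables conditioning.
#' @param min_events Minimum events required inside the window.
#' @return A `sample_summary`: list with `median_fluorescence`,
#'   `n_events_used`, `scatter_reference`, `gating_coverage` and the
#'   sample's metadata.
#' @export
size_conditioned_median <- function(events, scatter_reference = NULL,
                                    window_halfwidth = Inf, min_events = 100) {
  if (nrow(events) == 0) stop("empty event table", call. = FALSE)
  if (is.finite(window_halfwidth)) {
    if (is.null(scatter_reference)) {
      stop("scatter_reference required for a finite window", call. = FALSE)
    }
    keep <- abs(events$FSC - scatter_reference) <= window_halfwidth
  } else {
    keep <- rep(TRUE, nrow(events))
  }
  n_used <- sum(keep)
  if (n_used < min_events) {
    stop(sprintf(
      "only %d events in the scatter window (need >= %d); widen the window",
      n_used, min_events), call. = FALSE)
  }
  structure(
    list(median_fluorescence = stats::median(events$FL1[keep]),
         n_events_used = n_used,
         scatter_reference = if (is.finite(window_halfwidth)) scatter_reference else NA_real_,
         gating_coverage = n_used / nrow(events),
         gate = attr(events, "gate"),
         context_label = attr(events, "context_label"),
         iptg_uM = attr(events, "iptg_uM"),
         role = attr(events, "role")),
    class = "sample_summary"
  )
}

#' Preprocess one sample: density gate, then size-conditioned median
#'
#' @inheritParams scatter_gate
#' @inheritParams size_conditioned_median
#' @return A `sample_summary`.
#' @export
summarize_sample <- function(events, coverage = 0.5, scatter_reference = NULL,
                             window_halfwidth = Inf, min_events = 100,
                             bins = 64) {
  gated <- scatter_gate(events, coverage = coverage, bins = bins)
  size_conditioned_median(gated, scatter_reference = scatter_reference,
                          window_halfwidth = window_halfwidth,
                          min_events = min_events)
}
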