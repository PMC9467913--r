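# Binding-event extraction and acquisition statistics.
#
# A binding event is the set of valid final-iteration localizations that
# share a trace ID (TID). The instrument terminates a trace after a
# predefined number of non-valid localization attempts; the time stamp of
# the first of those trailing non-valid attempts defines the event end.

#' Group localizations into binding events
#'
#' Takes the full record stream (valid and non-valid rows are both needed:
#' the valid final-iteration rows define event membership, the non-valid
#' rows define end times) and returns one event per trace ID that has at
#' least one valid final-iteration localization.
#'
#' The event start is the time stamp of the first valid final-iteration
#' localization; the end is the time stamp of the first non-valid attempt
#' with the same trace ID at or after the last valid localization, falling
#' back to the last valid time stamp when no such attempt was exported.
#'
#' @param ds an [mfx_dataset] (unfiltered; the final-iteration/validity
#'   filter is applied internally).
#' @return data.frame of class `mfx_events`, one row per event, sorted by
#'   `t_start`, with columns `tid`, `t_start`, `t_end`, `n` (valid
#'   final-iteration localizations) and mean position `x`, `y`[, `z`];
#'   attribute `locs` holds the member localization table.
#' @export
extract_events <- function(ds) {
  stopifnot(inherits(ds, "mfx_dataset"))
  rec <- ds$records
  axis_names <- c("x", "y", "z")[seq_len(ds$ndim)]
  valid <- rec[rec$vld & rec$itr == ds$final_iteration, , drop = FALSE]
  if (nrow(valid) == 0L) {
    ev <- data.frame(tid = integer(0), t_start = numeric(0),
                     t_end = numeric(0), n = integer(0))
    for (a in axis_names) ev[[a]] <- numeric(0)
    return(structure(ev, locs = valid, class = c("mfx_events", "data.frame")))
  }
  invalid <- rec[!rec$vld, , drop = FALSE]
  tids <- unique(valid$tid)
  rows <- lapply(tids, function(id) {
    v <- valid[valid$tid == id, , drop = FALSE]
    last_valid <- max(v$tim)
    cand <- invalid$tim[invalid$tid == id & invalid$tim >= last_valid]
    t_end <- if (length(cand) > 0) min(cand) else last_valid
    out <- data.frame(tid = id, t_start = min(v$tim), t_end = t_end,
                      n = nrow(v))
    for (a in axis_names) out[[a]] <- mean(v[[a]])
    out
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$t_start), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, locs = valid, class = c("mfx_events", "data.frame"))
}

#' Median time between consecutive binding events
#'
#' For consecutive valid events (ordered by start time), the gap is the
#' start time of the later event minus the end time of the earlier one.
#' The statistic is the median gap over the first `max_events` events
#' (first 100 by default; all events when fewer are available). Negative
#' raw gaps — overlapping traces — are clipped to zero with a warning.
#'
#' @param events an `mfx_events` table from [extract_events()].
#' @param max_events number of leading events entering the median.
#' @return median gap in seconds; `NA` with a warning for fewer than two
#'   events.
#' @export
time_between_events <- function(events, max_events = 100) {
  if (nrow(events) < 2L) {
    warning("need at least two events to compute t_btw")
    return(NA_real_)
  }
  ev <- events[seq_len(min(nrow(events), max_events)), , drop = FALSE]
  gaps <- ev$t_start[-1L] - ev$t_end[-nrow(ev)]
  if (any(gaps < 0)) {
    warning(sum(gaps < 0), " negative inter-event gap(s) clipped to 0")
    gaps <- pmax(gaps, 0)
  }
  stats::median(gaps)
}

#' Median center-frequency ratio of the valid final-iteration localizations
#'
#' The CFR — emission frequency at the central position of the excitation
#' pattern over the mean frequency at the outer positions — is computed by
#' the instrument and exported per localization; the dataset statistic is
#' the median over all valid last-iteration records.
#'
#' @param ds an [mfx_dataset] with a `cfr` column.
#' @return median CFR (dimensionless).
#' @export
median_cfr <- function(ds) {
  .median_final_valid(ds, "cfr")
}

#' Median background emission frequency
#'
#' The background frequency f_bg is estimated continuously by the
#' instrument between valid events and exported with each record; the
#' dataset statistic is the median over valid last-iteration records.
#'
#' @param ds an [mfx_dataset] with an `fbg` column.
#' @return median f_bg in Hz.
#' @export
median_fbg <- function(ds) {
  .median_final_valid(ds, "fbg")
}

.median_final_valid <- function(ds, col) {
  stopifnot(inherits(ds, "mfx_dataset"))
  if (!col %in% names(ds$records)) {
    stop("dataset has no ", col, " column")
  }
  keep <- ds$records$vld & ds$records$itr == ds$final_iteration
  vals <- ds$records[[col]][keep]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no valid final-iteration ", col, " values")
  stats::median(vals)
}

#' Per-measurement event summary
#'
#' @param ds an [mfx_dataset].
#' @param max_events leading events used for t_btw (default 100).
#' @return list of class `mfx_event_summary` with `t_btw` (s),
#'   `median_cfr`, `median_fbg` (Hz; `NA` when the column is absent) and
#'   `n_events`.
#' @export
event_summary <- function(ds, max_events = 100) {
  events <- extract_events(ds)
  has <- function(col) col %in% names(ds$records) &&
    any(is.finite(ds$records[[col]]))
  structure(list(
    t_btw = if (nrow(events) >= 2L) time_between_events(events, max_events)
            else NA_real_,
    median_cfr = if (has("cfr")) median_cfr(ds) else NA_real_,
    median_fbg = if (has("fbg")) median_fbg(ds) else NA_real_,
    n_events = nrow(events)
  ), class = "mfx_event_summary")
}

#' @export
print.mfx_event_summary <- function(x, ...) {
  cat(sprintf(
    "events: %d | t_btw %.4g s | median CFR %.4g | median f_bg %.4g Hz\n",
    x$n_events, x$t_btw, x$median_cfr, x$median_fbg))
  invisible(x)
}
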