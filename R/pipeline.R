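# End-to-end analysis pipeline: filter -> events -> precision -> drift ->
# FRC -> render, with per-stage toggles and seeded determinism.

#' Run the full analysis pipeline on one dataset
#'
#' Applies the final-iteration/validity filter, extracts binding events,
#' and (as toggled) computes the event summary (t_btw, median CFR, median
#' f_bg), localization precisions before and after drift correction, the
#' FRC resolution on combined localizations, and rendered images. Drift
#' correction precedes the reported precision/FRC values; the
#' pre-correction precision is reported alongside for comparison.
#'
#' @param ds an [mfx_dataset] or a path readable by [read_records()].
#' @param stages character vector out of `"events"`, `"precision"`,
#'   `"drift"`, `"frc"`, `"render"`.
#' @param drift_window,drift_overlap windowing for [estimate_drift()].
#' @param frc_pixel,frc_repeats FRC settings (see [frc_resolution()]).
#' @param render_bin 2D histogram bin, nm.
#' @param seed seed for the FRC splits.
#' @param output_dir if non-NULL, the report is written as JSON and
#'   rendered images as TIFF into this directory.
#' @return list of class `mfx_report`; entries for disabled stages are
#'   absent.
#' @export
run_pipeline <- function(ds,
                         stages = c("events", "precision", "drift", "frc"),
                         drift_window = 2000, drift_overlap = 0.5,
                         frc_pixel = 2, frc_repeats = 10,
                         render_bin = 4, seed = 1, output_dir = NULL) {
  if (is.character(ds)) ds <- read_records(ds)
  stopifnot(inherits(ds, "mfx_dataset"))
  report <- list(seed = seed,
                 n_records = nrow(ds$records),
                 n_final_valid = nrow(filter_final_valid(ds)$records),
                 ndim = ds$ndim)
  events <- extract_events(ds)
  report$n_events <- nrow(events)
  if ("events" %in% stages) {
    s <- event_summary(ds)
    report$events <- list(t_btw = s$t_btw, median_cfr = s$median_cfr,
                          median_fbg = s$median_fbg,
                          n_events = s$n_events)
  }
  if ("precision" %in% stages) {
    p <- precision_summary(events)
    report$precision_raw <- p[c("sigma_r", "sigma_rc", "sigma_z",
                                "sigma_zc", "n_events_used")]
  }
  corrected <- events
  if ("drift" %in% stages) {
    trace <- tryCatch(
      estimate_drift(events, target_per_window = drift_window,
                     overlap_fraction = drift_overlap),
      error = function(e) {
        warning("drift stage skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(trace)) {
      corrected <- correct_drift(events, trace)
      report$drift <- list(
        n_windows = length(trace$times),
        amplitude = apply(trace$offsets, 2, function(o) diff(range(o))))
      if ("precision" %in% stages) {
        p <- precision_summary(corrected)
        report$precision <- p[c("sigma_r", "sigma_rc", "sigma_z",
                                "sigma_zc", "n_events_used")]
      }
    }
  }
  if ("frc" %in% stages) {
    pos <- combined_positions(corrected)
    report$frc <- tryCatch(
      list(resolution = frc_resolution(pos, pixel = frc_pixel,
                                       n_repeats = frc_repeats,
                                       seed = seed)$resolution,
           pixel = frc_pixel, n_repeats = frc_repeats),
      error = function(e) {
        warning("FRC stage skipped: ", conditionMessage(e))
        NULL
      })
  }
  if ("render" %in% stages && !is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    img <- histogram_2d(as.matrix(corrected[, c("x", "y")]),
                        bin = render_bin)
    img_path <- file.path(output_dir, "rendered_2d.tiff")
    write_image_tiff(img, img_path)
    report$render <- list(path_2d = img_path, bin = render_bin)
    if (ds$ndim == 3L) {
      img3 <- render_3d(as.matrix(corrected[, c("x", "y", "z")]))
      path3 <- file.path(output_dir, "rendered_3d.tiff")
      write_image_tiff(img3, path3)
      report$render$path_3d <- path3
    }
  }
  class(report) <- "mfx_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}

#' @export
print.mfx_report <- function(x, ...) {
  cat(sprintf("MINFLUX analysis report (%dD, %d events)\n",
              x$ndim, x$n_events))
  if (!is.null(x$events)) {
    cat(sprintf("  t_btw %.4g s | median CFR %.4g | median f_bg %.4g Hz\n",
                x$events$t_btw, x$events$median_cfr, x$events$median_fbg))
  }
  p <- x$precision %||% x$precision_raw
  if (!is.null(p)) {
    cat(sprintf("  sigma_r %.3g nm, sigma_rc %.3g nm (%d events)\n",
                p$sigma_r, p$sigma_rc, p$n_events_used))
  }
  if (!is.null(x$frc)) {
    cat(sprintf("  FRC resolution %.3g nm\n", x$frc$resolution))
  }
  invisible(x)
}

#' Analyze a series of measurements varying one parameter
#'
#' Mirrors parameter-exploration series in which laser power, pinhole
#' size or imager concentration is varied while everything else is kept
#' constant: each dataset is summarized and the results are returned in a
#' long-format table keyed by the varied parameter.
#'
#' @param datasets list of [mfx_dataset] objects (or paths).
#' @param varied name of the varied parameter (looked up in each
#'   dataset's metadata unless `values` is given).
#' @param values values of the varied parameter, one per dataset.
#' @return data.frame with columns `varied`, `value`, `t_btw`,
#'   `median_cfr`, `median_fbg`, `sigma_r`, `sigma_rc`, `n_events`.
#' @export
run_measurement_series <- function(datasets, varied, values = NULL) {
  if (length(datasets) < 1L) stop("need at least one dataset")
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    if (is.character(ds)) ds <- read_records(ds)
    value <- if (!is.null(values)) values[i]
             else ds$metadata[[varied]] %||% NA_real_
    s <- event_summary(ds)
    p <- precision_summary(ds)
    data.frame(varied = varied, value = value, t_btw = s$t_btw,
               median_cfr = s$median_cfr, median_fbg = s$median_fbg,
               sigma_r = p$sigma_r, sigma_rc = p$sigma_rc,
               n_events = s$n_events)
  })
  do.call(rbind, rows)
}
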