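# Reading, writing and filtering of MINFLUX localization export tables.
#
# The open tabular schema used throughout the package: one row per
# localization *attempt* with columns
#   tid  integer trace identifier (one binding event per trace)
#   tim  time stamp in seconds from acquisition start
#   vld  validity flag (1 = valid localization, 0 = discarded attempt)
#   itr  iteration index (0 = prelocalization)
#   x, y[, z]  estimated position in nanometers (may be NA for vld = 0)
# and optional columns efo (effective emission frequency, Hz), fbg
# (background emission frequency, Hz) and cfr (center-frequency ratio).

MANDATORY_COLS <- c("tid", "tim", "vld", "itr", "x", "y")
OPTIONAL_COLS <- c("z", "efo", "fbg", "cfr")

#' Construct a MINFLUX localization dataset
#'
#' Bundles a table of localization attempts with the acquisition geometry
#' (2D or 3D), the index of the final MINFLUX iteration and free-form
#' metadata. Records are kept sorted by time stamp.
#'
#' @param records data.frame with columns `tid`, `tim`, `vld`, `itr`, `x`,
#'   `y` and optionally `z`, `efo`, `fbg`, `cfr`. `vld` may be logical or
#'   0/1 integer.
#' @param ndim 2 or 3; inferred from the presence of a `z` column if `NULL`.
#' @param final_iteration index of the last MINFLUX iteration (4 in the
#'   default 2D sequence, 9 in 3D); taken as `max(itr)` if `NULL`.
#' @param metadata named list of free-form acquisition metadata (laser
#'   power, pinhole size, imager concentration, ...).
#' @return An object of class `mfx_dataset`: a list with elements
#'   `records`, `ndim`, `final_iteration`, `metadata`.
#' @export
mfx_dataset <- function(records, ndim = NULL, final_iteration = NULL,
                        metadata = list()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$tid <- as.integer(records$tid)
  records$vld <- as.logical(records$vld)
  records$itr <- as.integer(records$itr)
  if (is.null(ndim)) ndim <- if ("z" %in% names(records)) 3L else 2L
  ndim <- as.integer(ndim)
  if (!ndim %in% c(2L, 3L)) stop("ndim must be 2 or 3")
  if (ndim == 3L && !"z" %in% names(records)) {
    stop("ndim = 3 requires a z column")
  }
  if (nrow(records) > 0L) {
    if (any(records$tim < 0, na.rm = TRUE)) stop("tim must be >= 0")
    if (any(records$itr < 0, na.rm = TRUE)) stop("itr must be >= 0")
    if ("cfr" %in% names(records) &&
        any(records$cfr < 0, na.rm = TRUE)) {
      stop("cfr must be >= 0 where present")
    }
    if (is.unsorted(records$tim)) {
      records <- records[order(records$tim), , drop = FALSE]
    }
    rownames(records) <- NULL
  }
  if (is.null(final_iteration)) {
    final_iteration <- if (nrow(records) > 0L) max(records$itr) else 0L
  }
  structure(
    list(records = records, ndim = ndim,
         final_iteration = as.integer(final_iteration),
         metadata = metadata),
    class = "mfx_dataset"
  )
}

#' @export
print.mfx_dataset <- function(x, ...) {
  r <- x$records
  n_valid_final <- sum(r$vld & r$itr == x$final_iteration)
  cat(sprintf("MINFLUX dataset: %d localization attempts (%dD)\n",
              nrow(r), x$ndim))
  cat(sprintf("  final iteration %d; %d valid final-iteration localizations\n",
              x$final_iteration, n_valid_final))
  if (nrow(r) > 0L) {
    cat(sprintf("  time span %.3f .. %.3f s; %d traces\n",
                min(r$tim), max(r$tim), length(unique(r$tid))))
  }
  invisible(x)
}

#' Read a MINFLUX export table
#'
#' Reads the package's open CSV schema (one row per localization attempt).
#' A JSON sidecar `<path>.meta.json`, if present, supplies `ndim`,
#' `final_iteration` and metadata; otherwise the dimensionality is inferred
#' from the presence of a `z` column and the final iteration from
#' `max(itr)`. Records are re-sorted by time stamp with a warning if the
#' file is not time-ordered. Optional columns that are absent stay absent
#' (they are not filled with zeros).
#'
#' @param path path to a CSV localization table.
#' @return An [mfx_dataset].
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) > 0L && is.unsorted(records$tim)) {
    warning("time stamps not monotone; re-sorting records by tim")
  }
  ndim <- NULL
  final_iteration <- NULL
  metadata <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    ndim <- meta$ndim
    final_iteration <- meta$final_iteration
    metadata <- meta$metadata %||% list()
  }
  mfx_dataset(records, ndim = ndim, final_iteration = final_iteration,
              metadata = metadata)
}

#' Write a MINFLUX export table
#'
#' Writes the CSV schema read by [read_records()] plus a JSON metadata
#' sidecar `<path>.meta.json` carrying `ndim`, `final_iteration` and the
#' dataset metadata, so a round trip reproduces the dataset.
#'
#' @param ds an [mfx_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(ds, path) {
  stopifnot(inherits(ds, "mfx_dataset"))
  records <- ds$records
  records$vld <- as.integer(records$vld)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  meta <- list(ndim = ds$ndim, final_iteration = ds$final_iteration,
               metadata = ds$metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a MINFLUX iteration-sequence description
#'
#' Iteration sequences control the iterative zoom-in of the microscope and
#' are described in a JSON file with one entry per iteration (including the
#' prelocalization, whose targeted-coordinate-pattern diameter `L` is
#' null). Each entry carries `L` (nm), `photon_limit`, `dwell_ms`,
#' `cfr_limit` (a number, or `"off"` for no CFR filtering) and
#' `power_factor`.
#'
#' @param path path to a sequence JSON file.
#' @return An object of class `mfx_sequence`: a data.frame with one row per
#'   iteration and columns `id`, `L`, `photon_limit`, `dwell_ms`,
#'   `cfr_limit` (NA when off) and `power_factor`, plus attribute `ndim`.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(spec$iterations) || length(spec$iterations) == 0L) {
    stop("sequence file has no iterations")
  }
  rows <- lapply(seq_along(spec$iterations), function(i) {
    it <- spec$iterations[[i]]
    if (!("L" %in% names(it))) {
      stop("iteration entry ", i, " is missing L")
    }
    cfr_limit <- it$cfr_limit %||% "off"
    data.frame(
      id = it$id %||% paste0("iteration_", i - 1L),
      L = if (is.null(it$L)) NA_real_ else as.numeric(it$L),
      photon_limit = as.numeric(it$photon_limit %||% NA_real_),
      dwell_ms = as.numeric(it$dwell_ms %||% NA_real_),
      cfr_limit = if (identical(cfr_limit, "off")) NA_real_
                  else as.numeric(cfr_limit),
      power_factor = as.numeric(it$power_factor %||% 1),
      stringsAsFactors = FALSE
    )
  })
  seq_df <- do.call(rbind, rows)
  L_iter <- seq_df$L[!is.na(seq_df$L)]
  if (length(L_iter) > 1L && any(diff(L_iter) >= 0)) {
    warning("TCP diameter L is not strictly decreasing over iterations")
  }
  structure(seq_df, ndim = spec$ndim %||% NA_integer_,
            class = c("mfx_sequence", "data.frame"))
}

#' Keep only valid final-iteration localizations
#'
#' All quantification uses only records of the last MINFLUX iteration
#' (fourth in 2D, ninth in 3D, after one prelocalization) that the
#' instrument flagged as valid (`VLD = 1`). Record order is preserved; the
#' result is an empty dataset with a warning when nothing survives.
#'
#' @param ds an [mfx_dataset] with `final_iteration` set.
#' @return An [mfx_dataset] containing only the valid final-iteration rows.
#' @export
filter_final_valid <- function(ds) {
  stopifnot(inherits(ds, "mfx_dataset"))
  keep <- ds$records$vld & ds$records$itr == ds$final_iteration
  records <- ds$records[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(records) == 0L && nrow(ds$records) > 0L) {
    warning("no valid final-iteration localizations survive the filter")
  }
  mfx_dataset(records, ndim = ds$ndim,
              final_iteration = ds$final_iteration, metadata = ds$metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
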