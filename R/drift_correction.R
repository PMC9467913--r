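# Sample-drift correction by redundant cross-correlation.
#
# Events are divided into overlapping time windows, each window is
# rendered (Gaussian peak of SD 2 nm per event position), shifts between
# all window pairs are measured from the fitted cross-correlation peak,
# and the per-window drift offsets that satisfy all pairwise shifts are
# found in a least-squares sense. A natural cubic spline through the
# (window center time, offset) knots is evaluated at every event time and
# subtracted from the coordinates.

#' Divide events into overlapping index windows
#'
#' @param events an `mfx_events` table (or anything with rows ordered by
#'   time).
#' @param target_per_window events per window (default 2000).
#' @param overlap_fraction fraction of events shared by consecutive
#'   windows (default 0.5).
#' @return list of integer index vectors covering all events; a single
#'   window (with a warning) when there are too few events for two.
#' @export
window_events <- function(events, target_per_window = 2000,
                          overlap_fraction = 0.5) {
  n <- nrow(events)
  w <- min(target_per_window, n)
  if (n <= target_per_window) {
    warning("too few events for more than one window")
    return(list(seq_len(n)))
  }
  stride <- max(1L, round(w * (1 - overlap_fraction)))
  starts <- seq(1L, n - w + 1L, by = stride)
  if (starts[length(starts)] + w - 1L < n) {
    starts <- c(starts, n - w + 1L)
  }
  lapply(starts, function(s) seq(s, s + w - 1L))
}

#' Render positions as a Gaussian-peak image
#'
#' Bins positions on a metric grid and convolves with an isotropic
#' Gaussian kernel (circular convolution, so total mass is exactly the
#' number of in-bounds positions).
#'
#' @param positions numeric matrix, one row per position, 2 or 3 columns
#'   (nm).
#' @param sigma Gaussian SD in nm (default 2, the rendering used for
#'   drift estimation).
#' @param pixel pixel/voxel size in nm.
#' @param bounds 2 x d matrix (rows lo, hi) of the rendered region;
#'   default: data range padded by 3*sigma.
#' @return `mfx_image`: list with `values` (d-dimensional array), `pixel`
#'   (nm) and `origin` (nm coordinates of the center of the first pixel).
#' @export
render_positions <- function(positions, sigma = 2, pixel = 1,
                             bounds = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("need at least one position")
  d <- ncol(positions)
  if (is.null(bounds)) {
    pad <- 3 * sigma + pixel
    bounds <- rbind(apply(positions, 2, min) - pad,
                    apply(positions, 2, max) + pad)
  }
  if (any(bounds[2, ] <= bounds[1, ])) stop("degenerate bounds")
  npix <- pmax(2L, ceiling((bounds[2, ] - bounds[1, ]) / pixel))
  arr <- .bin_positions(positions, bounds[1, ], pixel, npix)
  if (sigma > 0) arr <- .fft_blur(arr, sigma / pixel)
  structure(list(values = arr, pixel = pixel,
                 origin = bounds[1, ] + pixel / 2),
            class = "mfx_image")
}

# histogram counts on a regular grid; positions outside are dropped
.bin_positions <- function(positions, lo, pixel, npix) {
  d <- ncol(positions)
  idx <- floor(sweep(positions, 2, lo) / pixel) + 1
  ok <- rowSums(idx >= 1 & sweep(idx, 2, npix, "<=")) == d &
    rowSums(is.finite(idx)) == d
  idx <- idx[ok, , drop = FALSE]
  lin <- idx[, 1]
  mult <- npix[1]
  for (a in seq_len(d - 1) + 1) {
    lin <- lin + (idx[, a] - 1) * mult
    mult <- mult * npix[a]
  }
  array(tabulate(lin, nbins = prod(npix)), dim = npix)
}

# separable circular Gaussian blur with unit-sum kernel per axis
.fft_blur <- function(arr, sigma_px) {
  dims <- dim(arr)
  F <- stats::fft(arr)
  for (a in seq_along(dims)) {
    n <- dims[a]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_px^2))
    k <- k / sum(k)
    fk <- stats::fft(k)
    F <- F * fk[slice.index(F, a)]
  }
  Re(stats::fft(F, inverse = TRUE)) / prod(dims)
}

#' Shift between two rendered images from the cross-correlation peak
#'
#' Computes the spectral cross-correlation on a zero-padded grid (>= 2x
#' the image extent), locates the peak, and refines it per axis by a
#' Gaussian (log-quadratic) fit over a +/-`m`-pixel neighborhood. The fit
#' quality is the ratio of the peak height to the median correlation;
#' featureless correlations are flagged so the solver can drop them.
#'
#' @param img_i,img_j `mfx_image` objects on identical grids.
#' @param m half-width in pixels of the per-axis fit neighborhood.
#' @param quality_min minimum peak significance for `ok = TRUE` (a Gaussian correlation field peaks near 5; structured matches score far higher).
#' @return list with `shift` (nm; the displacement of `img_j` relative to
#'   `img_i`), `quality` and `ok`.
#' @export
pairwise_shift <- function(img_i, img_j, m = 3, quality_min = 8) {
  stopifnot(identical(dim(img_i$values), dim(img_j$values)),
            isTRUE(all.equal(img_i$pixel, img_j$pixel)))
  Fa <- .padded_fft(img_i$values)
  Fb <- .padded_fft(img_j$values)
  .shift_from_ffts(Fa, Fb, img_i$pixel, m = m, quality_min = quality_min)
}

# zero-padded (2x per axis) forward FFT of an image array
.padded_fft <- function(A) {
  dims <- dim(A)
  pdims <- 2L * dims
  Ap <- array(0, pdims)
  if (length(dims) == 2L) {
    Ap[seq_len(dims[1]), seq_len(dims[2])] <- A
  } else {
    Ap[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- A
  }
  stats::fft(Ap)
}

# cross-correlation peak location from precomputed padded FFTs
.shift_from_ffts <- function(Fa, Fb, pixel, m = 3, quality_min = 8) {
  pdims <- dim(Fa)
  # B(x) = A(x - d)  =>  ifft(fft(B) * Conj(fft(A))) peaks at +d
  C <- Re(stats::fft(Fb * Conj(Fa), inverse = TRUE)) / prod(pdims)
  dims <- pdims  # correlation lives on the padded grid
  peak <- arrayInd(which.max(C), pdims)[1, ]
  peak_val <- C[matrix(peak, 1)]
  med <- stats::median(C)
  spread <- stats::sd(C)
  quality <- if (spread > 0) (peak_val - med) / spread else 0
  shift_px <- numeric(length(dims))
  for (a in seq_along(dims)) {
    n <- pdims[a]
    offs <- -m:m
    idx_a <- ((peak[a] - 1 + offs) %% n) + 1
    sel <- lapply(seq_along(dims), function(b) peak[b])
    prof <- vapply(idx_a, function(i) {
      sel[[a]] <- i
      do.call(`[`, c(list(C), sel))
    }, numeric(1))
    shift_px[a] <- (peak[a] - 1) + .log_quad_vertex(offs, prof)
    if (shift_px[a] > n / 2) shift_px[a] <- shift_px[a] - n
  }
  list(shift = shift_px * pixel, quality = quality,
       ok = quality >= quality_min)
}

# vertex of a quadratic fitted to log(values); 0 on failure
.log_quad_vertex <- function(x, y) {
  pos <- y > max(y) * 1e-6 & y > 0
  if (sum(pos) < 3) return(0)
  fit <- stats::lm.fit(cbind(1, x[pos], x[pos]^2), log(y[pos]))
  a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
  if (!is.finite(a2) || a2 >= 0) return(0)
  v <- -a1 / (2 * a2)
  if (abs(v) > max(abs(x))) 0 else v
}

#' Least-squares drift offsets from pairwise window shifts
#'
#' Finds per-window offsets p minimizing
#' sum over pairs (i,j) of || p_j - p_i - d_ij ||^2, with the gauge
#' mean(p) = 0, and joins them with a natural cubic spline over the
#' window-center times.
#'
#' @param shifts data.frame with columns `i`, `j`, one shift column per
#'   axis (`dx`, `dy`[, `dz`]) and logical `ok`.
#' @param window_times window-center times, s (one per window).
#' @return `mfx_drift_trace`: list with `times`, `offsets` (windows x
#'   axes, nm) and the spline interpolants; evaluate with
#'   [eval_drift_trace()].
#' @export
solve_drift <- function(shifts, window_times) {
  W <- length(window_times)
  use <- shifts[shifts$ok, , drop = FALSE]
  if (nrow(use) == 0L) stop("no usable pairwise shifts")
  reached <- sort(unique(as.integer(c(use$i, use$j))))
  if (!identical(reached, seq_len(W))) {
    stop("shift graph does not connect windows: missing ",
         paste(setdiff(seq_len(W), reached), collapse = ", "))
  }
  axes <- intersect(c("dx", "dy", "dz"), names(shifts))
  A <- matrix(0, nrow(use) + 1L, W)
  for (r in seq_len(nrow(use))) {
    A[r, use$i[r]] <- -1
    A[r, use$j[r]] <- 1
  }
  A[nrow(use) + 1L, ] <- 1  # gauge: offsets sum to zero
  offsets <- vapply(axes, function(ax) {
    b <- c(use[[ax]], 0)
    stats::lm.fit(A, b)$coefficients
  }, numeric(W))
  offsets <- matrix(offsets, W, length(axes))
  splines <- lapply(seq_along(axes), function(a) {
    if (W >= 2L) stats::splinefun(window_times, offsets[, a],
                                  method = "natural")
    else function(t) rep(offsets[1, a], length(t))
  })
  structure(list(times = window_times, offsets = offsets,
                 splines = splines, n_axes = length(axes)),
            class = "mfx_drift_trace")
}

#' Evaluate a drift trace
#'
#' Times outside the knot span are clamped to the end knots (no spline
#' extrapolation).
#'
#' @param trace an `mfx_drift_trace` from [solve_drift()].
#' @param t times, s.
#' @return `length(t) x n_axes` matrix of offsets, nm.
#' @export
eval_drift_trace <- function(trace, t) {
  tc <- pmin(pmax(t, min(trace$times)), max(trace$times))
  out <- vapply(trace$splines, function(f) f(tc), numeric(length(tc)))
  matrix(out, length(tc), trace$n_axes)
}

#' Estimate sample drift from binding events
#'
#' Orchestrates windowing, rendering, pairwise shift estimation over all
#' window pairs and the least-squares solve.
#'
#' @param events an `mfx_events` table from [extract_events()].
#' @param target_per_window,overlap_fraction see [window_events()].
#' @param pixel rendering pixel, nm (default 1 in 2D, 2 in 3D).
#' @param sigma rendering Gaussian SD, nm (default 2).
#' @param quality_min pairwise-shift quality threshold.
#' @return an `mfx_drift_trace`.
#' @export
estimate_drift <- function(events, target_per_window = 2000,
                           overlap_fraction = 0.5, pixel = NULL,
                           sigma = 2, quality_min = 8) {
  axes <- intersect(c("x", "y", "z"), names(events))
  d <- length(axes)
  if (is.null(pixel)) pixel <- if (d == 3L) 2 else 1
  wins <- window_events(events, target_per_window, overlap_fraction)
  if (length(wins) < 2L) {
    stop("drift estimation needs at least two windows; got ",
         length(wins))
  }
  pos <- as.matrix(events[, axes, drop = FALSE])
  pad <- 3 * sigma + pixel
  bounds <- rbind(apply(pos, 2, min) - pad, apply(pos, 2, max) + pad)
  ffts <- lapply(wins, function(w) {
    img <- render_positions(pos[w, , drop = FALSE], sigma = sigma,
                            pixel = pixel, bounds = bounds)
    .padded_fft(img$values)
  })
  times <- vapply(wins, function(w) stats::median(events$t_start[w]),
                  numeric(1))
  pairs <- utils::combn(length(wins), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    s <- .shift_from_ffts(ffts[[i]], ffts[[j]], pixel,
                          quality_min = quality_min)
    out <- data.frame(i = i, j = j, quality = s$quality, ok = s$ok)
    for (a in seq_len(d)) out[[paste0("d", axes[a])]] <- s$shift[a]
    out
  })
  solve_drift(do.call(rbind, rows), times)
}

#' Subtract a drift trace from event positions
#'
#' Each event (and its member localizations) is shifted by the trace
#' evaluated at the event start time; events are short compared to drift
#' timescales, so one offset per event suffices.
#'
#' @param events an `mfx_events` table.
#' @param trace an `mfx_drift_trace`.
#' @return the corrected `mfx_events` table.
#' @export
correct_drift <- function(events, trace) {
  axes <- intersect(c("x", "y", "z"), names(events))[seq_len(trace$n_axes)]
  off <- eval_drift_trace(trace, events$t_start)
  for (a in seq_along(axes)) {
    events[[axes[a]]] <- events[[axes[a]]] - off[, a]
  }
  locs <- attr(events, "locs")
  if (!is.null(locs) && nrow(locs) > 0L) {
    ev_off <- off[match(locs$tid, events$tid), , drop = FALSE]
    for (a in seq_along(axes)) {
      locs[[axes[a]]] <- locs[[axes[a]]] - ev_off[, a]
    }
    attr(events, "locs") <- locs
  }
  events
}
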