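# Fourier ring correlation resolution.
#
# The dataset of combined localizations (one mean x/y position per trace
# ID) is split at random into two halves, each half is rendered as a 2D
# count histogram, and the correlation of the two Fourier transforms is
# averaged on rings of constant spatial frequency. The inverse of the
# frequency where the curve drops below 1/7 is the FRC resolution; random
# splits are repeated and the resolutions averaged. Combined (per-event)
# localizations are used because repeated localizations within one binding
# event are not independent and would otherwise pin the FRC to the single
# localization precision.

#' Combined (per-event) lateral positions
#'
#' @param events an `mfx_events` table from [extract_events()].
#' @return matrix with one `(x, y)` row per event (z is ignored).
#' @export
combined_positions <- function(events) {
  cbind(x = events$x, y = events$y)
}

#' Fourier ring correlation curve of two images
#'
#' FRC(q) = Re sum(F_A conj(F_B)) / sqrt(sum|F_A|^2 sum|F_B|^2) over rings
#' of one frequency bin width.
#'
#' @param img_a,img_b `mfx_image` objects (or plain matrices) on identical
#'   square grids.
#' @param pixel pixel size in nm (taken from the images when available).
#' @return data.frame of class `mfx_frc_curve` with `freq` (ring center
#'   spatial frequency, 1/nm) and `frc`.
#' @export
frc_curve <- function(img_a, img_b, pixel = NULL) {
  A <- if (inherits(img_a, "mfx_image")) img_a$values else img_a
  B <- if (inherits(img_b, "mfx_image")) img_b$values else img_b
  if (is.null(pixel)) {
    pixel <- if (inherits(img_a, "mfx_image")) img_a$pixel else 1
  }
  if (!identical(dim(A), dim(B))) stop("image grids differ")
  if (length(dim(A)) != 2L || dim(A)[1] != dim(A)[2]) {
    stop("FRC needs square 2D images")
  }
  n <- dim(A)[1]
  FA <- stats::fft(A)
  FB <- stats::fft(B)
  f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # DFT frequencies, cycles/grid
  ring <- round(sqrt(outer(f1^2, f1^2, "+")))
  ring <- pmin(ring, n)  # guard; corners beyond Nyquist are dropped below
  kmax <- n %/% 2
  sums <- rowsum(cbind(as.vector(Re(FA * Conj(FB))),
                       as.vector(Mod(FA)^2), as.vector(Mod(FB)^2)),
                 group = as.vector(ring))
  keep <- as.integer(rownames(sums)) <= kmax
  sums <- sums[keep, , drop = FALSE]
  ridx <- as.integer(rownames(sums))
  num_r <- pa_r <- pb_r <- numeric(kmax + 1)
  num_r[ridx + 1] <- sums[, 1]
  pa_r[ridx + 1] <- sums[, 2]
  pb_r[ridx + 1] <- sums[, 3]
  frc <- num_r / sqrt(pa_r * pb_r)
  frc[!is.finite(frc)] <- 0
  out <- data.frame(freq = (0:kmax) / (n * pixel), frc = frc)
  out <- out[-1L, , drop = FALSE]  # drop the DC term
  rownames(out) <- NULL
  structure(out, pixel = pixel, n = n,
            class = c("mfx_frc_curve", "data.frame"))
}

# first frequency where the curve drops below `threshold` and stays below
# for one further ring; linear interpolation between the bracketing rings.
.frc_crossing <- function(curve, threshold = 1 / 7) {
  below <- curve$frc < threshold
  k <- which(below & c(below[-1L], TRUE))
  k <- k[k > 1L]
  if (length(k) == 0L) return(NA_real_)
  k <- k[1L]
  f0 <- curve$freq[k - 1L]; f1 <- curve$freq[k]
  c0 <- curve$frc[k - 1L]; c1 <- curve$frc[k]
  if (c0 <= threshold) return(f0)
  f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
}

#' FRC resolution of a set of combined localizations
#'
#' Repeats a random half-split of the positions, renders each half as a
#' count histogram on a power-of-two square grid, computes the FRC curve
#' and locates the 1/7 crossing; the per-split resolutions are averaged.
#'
#' @param positions matrix of combined `(x, y)` positions, nm.
#' @param pixel histogram pixel size, nm (default 2).
#' @param n_repeats number of random splits (default 10).
#' @param seed RNG seed; fixed seed gives a deterministic result.
#' @param min_positions refuse below this many positions (default 100).
#' @param threshold correlation threshold (default 1/7).
#' @return list of class `mfx_frc_result` with `resolution` (nm, mean over
#'   splits), `per_repeat` (nm), `n_repeats`, `threshold`, and the last
#'   split's curve in `curve`. Splits whose curve never crosses the
#'   threshold are excluded with a warning (resolution at the Nyquist
#'   limit cannot be quantified).
#' @export
frc_resolution <- function(positions, pixel = 2, n_repeats = 10, seed = 1,
                           min_positions = 100, threshold = 1 / 7) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  npos <- nrow(positions)
  if (npos < min_positions) {
    stop("need at least ", min_positions, " combined positions")
  }
  # anchor bins at pixel multiples so grid-compatible transforms
  # (whole-pixel translations, 90-degree rotations) are exactly invariant
  lo <- floor(apply(positions, 2, min) / pixel) * pixel
  hi <- apply(positions, 2, max)
  n_grid <- 2^ceiling(log2(max((hi - lo) / pixel) + 2))
  npix <- c(n_grid, n_grid)
  set.seed(seed)
  res <- numeric(n_repeats)
  curve <- NULL
  for (r in seq_len(n_repeats)) {
    half <- sample(npos, npos %/% 2)
    ha <- .bin_positions(positions[half, , drop = FALSE], lo, pixel, npix)
    hb <- .bin_positions(positions[-half, , drop = FALSE], lo, pixel, npix)
    curve <- frc_curve(ha, hb, pixel = pixel)
    q <- .frc_crossing(curve, threshold)
    res[r] <- if (is.na(q) || q <= 0) NA_real_ else 1 / q
  }
  if (anyNA(res)) {
    warning(sum(is.na(res)),
            " split(s) never crossed the threshold (resolution at the ",
            "Nyquist limit); excluded from the average")
  }
  structure(list(resolution = mean(res, na.rm = TRUE),
                 per_repeat = res, n_repeats = n_repeats,
                 threshold = threshold, pixel = pixel, curve = curve),
            class = "mfx_frc_result")
}

#' @export
print.mfx_frc_result <- function(x, ...) {
  cat(sprintf("FRC resolution: %.3g nm (mean of %d random splits, %g-nm pixels)\n",
              x$resolution, x$n_repeats, x$pixel))
  invisible(x)
}
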