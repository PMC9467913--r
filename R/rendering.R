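# Image rendering of localization data.
#
# 2D data are displayed as plain count histograms (4 nm bins for
# overviews, 1 nm for close-ups); 3D data are rendered by replacing each
# localization with a Gaussian peak of sigma 5 nm after scaling the z
# coordinate by 0.7, the refractive-index mismatch convention of the
# acquisition. Stored coordinates are never modified: the z scaling is
# applied at render time only, so precision statistics are unaffected.

#' 2D localization histogram
#'
#' Integer counts per bin with half-open bin intervals `[lo, hi)`. The bin
#' origin is anchored at the data bounding-box minimum rounded down to a
#' bin multiple, so rendering is deterministic and a coarse image is an
#' exact block-sum of a fine image rendered over the same bounds.
#'
#' @param positions matrix with columns x, y (nm); extra columns ignored.
#' @param bin bin size, nm (default 4).
#' @param bounds optional 2 x 2 matrix (rows lo, hi) fixing the rendered
#'   region; out-of-bounds positions are dropped.
#' @return `mfx_image` with integer counts; sum of counts equals the
#'   number of in-bounds positions.
#' @export
histogram_2d <- function(positions, bin = 4, bounds = NULL) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  positions <- positions[stats::complete.cases(positions), , drop = FALSE]
  if (nrow(positions) == 0L) {
    warning("no positions to render")
    return(structure(list(values = matrix(0, 1, 1), pixel = bin,
                          origin = c(0, 0)), class = "mfx_image"))
  }
  if (is.null(bounds)) {
    lo <- floor(apply(positions, 2, min) / bin) * bin
    hi <- apply(positions, 2, max)
    npix <- floor((hi - lo) / bin) + 1L  # max point stays in range
  } else {
    lo <- bounds[1, ]; hi <- bounds[2, ]
    npix <- pmax(1L, ceiling((hi - lo) / bin - 1e-9))  # half-open [lo, hi)
  }
  arr <- .bin_positions(positions, lo, bin, npix)
  structure(list(values = arr, pixel = bin, origin = lo + bin / 2),
            class = "mfx_image")
}

#' 3D Gaussian rendering with axial scaling
#'
#' Scales z by `z_scale` (default 0.7), bins the positions into voxels
#' and convolves with an isotropic Gaussian of SD `sigma` (default 5 nm).
#' Intended for drift-corrected localizations.
#'
#' @param positions matrix with columns x, y, z (nm).
#' @param sigma Gaussian SD, nm.
#' @param z_scale axial scaling factor in (0, 1].
#' @param voxel voxel size, nm.
#' @return `mfx_image` with a 3D `values` array; total mass equals the
#'   position count.
#' @export
render_3d <- function(positions, sigma = 5, z_scale = 0.7, voxel = 2) {
  positions <- as.matrix(positions)
  if (ncol(positions) < 3L) {
    stop("render_3d needs x, y and z columns; use histogram_2d for 2D data")
  }
  if (z_scale <= 0 || z_scale > 1) stop("z_scale must be in (0, 1]")
  positions <- positions[stats::complete.cases(positions), 1:3,
                         drop = FALSE]
  positions[, 3] <- positions[, 3] * z_scale
  render_positions(positions, sigma = sigma, pixel = voxel)
}

#' Write a rendered image as TIFF
#'
#' 2D images become a single 32-bit float page, 3D arrays a multi-page
#' stack (one page per z plane). Pixel values are written as-is divided by
#' `scale`; the default scales the maximum to 1 so that any TIFF reader
#' accepts the file, and the scale is returned for exact recovery.
#'
#' @param img an `mfx_image`.
#' @param path output file path.
#' @param scale divisor applied before writing; `NULL` scales max to 1.
#' @return the scale used, invisibly.
#' @export
write_image_tiff <- function(img, path, scale = NULL) {
  vals <- img$values
  if (is.null(scale)) scale <- max(vals, 1e-12)
  vals <- vals / scale
  pages <- if (length(dim(vals)) == 3L) {
    lapply(seq_len(dim(vals)[3]), function(k) vals[, , k])
  } else vals
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}
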