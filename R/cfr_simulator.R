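# Physical simulation of the center-frequency ratio (CFR).
#
# The CFR reported by the instrument compares the emission frequency with
# the donut centered on the molecule against the mean frequency at the
# outer positions of the targeted coordinate pattern (TCP). For a molecule
# at the pattern center and a perfect donut zero the center exposure
# detects no signal, so any measured center frequency is background from
# freely diffusing imager. This module computes
#   h_eff,i = h_exc,i * h_det
# from vectorial (Richards-Wolf) focus fields: h_exc is the focal
# intensity of a circularly polarized charge-1 vortex beam (2D donut),
# h_det the emission PSF integrated over the back-projected confocal
# pinhole. Background per exposure is B_i = c * integral of h_eff,i dV,
# signal is I_i = h_eff,i(0,0,0), and
#   CFR = (B_center + I_center) / (B_outer_mean + I_outer_mean).

#' Optical configuration for the CFR simulator
#'
#' @param lambda_exc excitation wavelength, nm (default 642).
#' @param lambda_det detection wavelength, nm (default 680; pinhole Airy
#'   units refer to this wavelength).
#' @param na objective numerical aperture (default 1.4, oil immersion).
#' @param n_immersion immersion refractive index (default 1.518).
#' @param pinhole_au pinhole diameter in Airy units, 1 AU = 1.22 *
#'   lambda_det / NA in the sample plane (default 0.6).
#' @param grid_spacing sampling step, nm (default 25; a warning is issued
#'   above lambda_exc / (8 NA)).
#' @param grid_halfwidth half-width of the cubic computation domain, nm
#'   (default 3 * lambda_det / NA, beyond which contributions to the
#'   background integrals are negligible at the default pinholes).
#' @param quad_nodes Gauss-Legendre nodes of the aperture integral.
#' @return list of class `mfx_optics`.
#' @export
optical_config <- function(lambda_exc = 642, lambda_det = 680, na = 1.4,
                           n_immersion = 1.518, pinhole_au = 0.6,
                           grid_spacing = 25, grid_halfwidth = NULL,
                           quad_nodes = 96) {
  if (na <= 0 || na >= n_immersion) {
    stop("need 0 < NA < immersion refractive index")
  }
  if (is.null(grid_halfwidth)) grid_halfwidth <- 3 * lambda_det / na
  if (grid_spacing > lambda_exc / (8 * na)) {
    warning("grid spacing ", grid_spacing,
            " nm is coarse (> lambda/8NA); fields may be undersampled")
  }
  if (pinhole_au <= 0) stop("pinhole diameter must be > 0")
  structure(list(lambda_exc = lambda_exc, lambda_det = lambda_det,
                 na = na, n_immersion = n_immersion,
                 pinhole_au = pinhole_au, grid_spacing = grid_spacing,
                 grid_halfwidth = grid_halfwidth,
                 quad_nodes = as.integer(quad_nodes)),
            class = "mfx_optics")
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch, symmetric
# tridiagonal eigen decomposition).
.gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Focal intensity of a circularly polarized beam with vortex charge l via
# the Richards-Wolf integrals, evaluated on a (r, z) table. Azimuthal
# symmetry of the intensity is exact for circular polarization.
# Returns a list(r, z, I) with I a length(r) x length(z) matrix whose
# global maximum is scaled to 1.
.rw_radial_table <- function(r, z, lambda, na, n_imm, l = 0,
                             quad_nodes = 96) {
  k <- 2 * pi * n_imm / lambda
  alpha <- asin(na / n_imm)
  gl <- .gauss_legendre(quad_nodes, 0, alpha)
  th <- gl$nodes; w <- gl$weights
  ct <- cos(th); st <- sin(th)
  apod <- sqrt(ct) * st          # aplanatic factor x Jacobian
  fP <- apod * (1 + ct) / 2      # order l
  fQ <- apod * (1 - ct) / 2      # order l + 2
  fS <- apod * st                # order l + 1 (longitudinal)
  krs <- outer(k * st, r)        # quad_nodes x nr
  JP <- besselJ(krs, l)
  JQ <- besselJ(krs, l + 2)
  JS <- besselJ(krs, l + 1)
  I <- matrix(0, length(r), length(z))
  for (iz in seq_along(z)) {
    phase <- exp(1i * k * z[iz] * ct) * w
    P <- crossprod(JP, phase * fP)
    Q <- crossprod(JQ, phase * fQ)
    S <- crossprod(JS, phase * fS)
    I[, iz] <- Mod(P)^2 + Mod(Q)^2 + Mod(S)^2 / 2
  }
  list(r = r, z = z, I = I / max(I))
}

# axis of the cubic grid: symmetric, includes 0
.psf_axis <- function(cfg) {
  n <- ceiling(cfg$grid_halfwidth / cfg$grid_spacing)
  seq(-n, n) * cfg$grid_spacing
}

# expand a radial (r, z) table onto the cubic grid
.radial_to_grid <- function(tab, ax) {
  n <- length(ax)
  r_slice <- sqrt(outer(ax^2, ax^2, "+"))
  vals <- array(0, c(n, n, n))
  for (iz in seq_len(n)) {
    vals[, , iz] <- matrix(stats::approx(tab$r, tab$I[, iz],
                                         xout = as.vector(r_slice),
                                         rule = 2)$y, n, n)
  }
  vals
}

.radial_margin <- 400  # nm of extra radius kept in tables for TCP shifts

#' Donut-shaped excitation PSF
#'
#' Vectorial focal intensity of a circularly polarized vortex beam of
#' topological charge 1 (handedness matched to the polarization), computed
#' with the Richards-Wolf diffraction integral. The on-axis intensity is
#' exactly zero: all azimuthal field orders are nonzero, so every Bessel
#' term vanishes at r = 0.
#'
#' @param cfg an [optical_config()].
#' @return `mfx_psf`: list with `values` (3D array, peak normalized to 1),
#'   metric axes `x`, `y`, `z` (nm) and `spacing`; the underlying radial
#'   table is attached for exact off-grid evaluation.
#' @export
excitation_donut <- function(cfg) {
  ax <- .psf_axis(cfg)
  rmax <- sqrt(2) * max(ax) + .radial_margin
  r_tab <- seq(0, rmax, by = cfg$grid_spacing / 4)
  tab <- .rw_radial_table(r_tab, ax, cfg$lambda_exc, cfg$na,
                          cfg$n_immersion, l = 1,
                          quad_nodes = cfg$quad_nodes)
  structure(list(values = .radial_to_grid(tab, ax),
                 x = ax, y = ax, z = ax, spacing = cfg$grid_spacing,
                 normalization = "peak", kind = "excitation_donut"),
            class = "mfx_psf", radial = tab)
}

#' Confocal detection PSF
#'
#' Emission-wavelength focal intensity (vectorial, polarization-averaged)
#' integrated over the back-projected pinhole disc: each lateral slice is
#' convolved with a hard disc of diameter `pinhole_au` Airy units
#' (1 AU = 1.22 lambda_det / NA). Peak normalized to 1 on the axis.
#'
#' @param cfg an [optical_config()].
#' @return `mfx_psf` as in [excitation_donut()].
#' @export
detection_psf <- function(cfg) {
  ax <- .psf_axis(cfg)
  rmax <- sqrt(2) * max(ax) + .radial_margin
  r_tab <- seq(0, rmax, by = cfg$grid_spacing / 4)
  tab <- .rw_radial_table(r_tab, ax, cfg$lambda_det, cfg$na,
                          cfg$n_immersion, l = 0,
                          quad_nodes = cfg$quad_nodes)
  em <- .radial_to_grid(tab, ax)
  r_pinhole <- 0.5 * cfg$pinhole_au * 1.22 * cfg$lambda_det / cfg$na
  vals <- .disc_convolve(em, ax, r_pinhole)
  vals <- vals / max(vals)
  structure(list(values = vals, x = ax, y = ax, z = ax,
                 spacing = cfg$grid_spacing, normalization = "peak",
                 kind = "confocal_detection", pinhole_radius = r_pinhole),
            class = "mfx_psf")
}

# convolve each z slice with a hard disc of radius r_pinhole (nm),
# zero-padded FFT so nothing wraps around
.disc_convolve <- function(vals, ax, r_pinhole) {
  n <- length(ax)
  spacing <- ax[2] - ax[1]
  np <- stats::nextn(n + 2 * ceiling(r_pinhole / spacing) + 1, 2)
  cx <- c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) * spacing
  disc <- outer(cx^2, cx^2, "+") <= r_pinhole^2
  disc <- disc / sum(disc)
  Fd <- stats::fft(disc)
  out <- array(0, dim(vals))
  pad <- matrix(0, np, np)
  for (iz in seq_len(n)) {
    pad[] <- 0
    pad[seq_len(n), seq_len(n)] <- vals[, , iz]
    conv <- Re(stats::fft(stats::fft(pad) * Fd, inverse = TRUE)) / np^2
    out[, , iz] <- conv[seq_len(n), seq_len(n)]
  }
  # the disc kernel is centered at index (1,1); with symmetric axes the
  # slice center sits at (n+1)/2, which the circular kernel preserves
  pmax(out, 0)
}

#' Targeted coordinate pattern (TCP)
#'
#' @param L pattern diameter, nm (40 in the final iteration of the default
#'   sequences).
#' @param n_outer outer exposure count (default 6, equally spaced on the
#'   circle of radius L/2).
#' @param dwell_center_fraction share of exposure time spent at the
#'   center; the rest is split equally among the outer positions.
#' @return `mfx_tcp`: list with `L`, `positions` ((n_outer + 1) x 2, first
#'   row the center) and `dwell` fractions.
#' @export
tcp_pattern <- function(L, n_outer = 6,
                        dwell_center_fraction = 1 / (n_outer + 1)) {
  phi <- 2 * pi * (seq_len(n_outer) - 1) / n_outer
  positions <- rbind(c(0, 0), cbind(L / 2 * cos(phi), L / 2 * sin(phi)))
  dwell <- c(dwell_center_fraction,
             rep((1 - dwell_center_fraction) / n_outer, n_outer))
  structure(list(L = L, positions = positions, dwell = dwell),
            class = "mfx_tcp")
}

#' Effective PSF of one TCP exposure
#'
#' h_eff,i = h_exc (shifted to the exposure position) * h_det (kept
#' centered). The shifted excitation is evaluated from its radial table,
#' so no resampling error is introduced.
#'
#' @param h_exc donut PSF from [excitation_donut()].
#' @param h_det detection PSF from [detection_psf()] on the same grid.
#' @param exposure_pos lateral exposure position `(x, y)` in nm.
#' @return `mfx_psf` with the pointwise product (unnormalized).
#' @export
effective_psf <- function(h_exc, h_det, exposure_pos = c(0, 0)) {
  stopifnot(identical(dim(h_exc$values), dim(h_det$values)))
  tab <- attr(h_exc, "radial")
  if (is.null(tab)) stop("h_exc carries no radial table")
  ax <- h_exc$x
  r_need <- sqrt(2) * max(ax) + sqrt(sum(exposure_pos^2))
  if (r_need > max(tab$r)) {
    stop("exposure position shifts the donut beyond the sampled grid")
  }
  r_slice <- sqrt(outer((ax - exposure_pos[1])^2,
                        (ax - exposure_pos[2])^2, "+"))
  n <- length(ax)
  vals <- array(0, dim(h_exc$values))
  for (iz in seq_len(n)) {
    exc_sh <- matrix(stats::approx(tab$r, tab$I[, iz],
                                   xout = as.vector(r_slice),
                                   rule = 2)$y, n, n)
    vals[, , iz] <- exc_sh * h_det$values[, , iz]
  }
  structure(list(values = vals, x = ax, y = ax, z = ax,
                 spacing = h_exc$spacing, normalization = "product",
                 kind = "effective"),
            class = "mfx_psf")
}

#' Background intensity of one exposure
#'
#' B_i = integral of h_eff,i(x, y, z) * c dV, the expected emission rate
#' (per unit single-molecule brightness) of imager strands diffusing
#' through the effective excitation volume.
#'
#' @param h_eff effective PSF from [effective_psf()].
#' @param c_imager imager concentration, nM (1 nM = 6.022e-10
#'   molecules/nm^3).
#' @return background intensity, same relative units as the signal
#'   `h_eff(0, 0, 0)` of a single molecule.
#' @export
background_intensity <- function(h_eff, c_imager) {
  if (c_imager < 0) stop("concentration must be >= 0")
  c_nm3 <- c_imager * 6.022e-10
  sum(h_eff$values) * h_eff$spacing^3 * c_nm3
}

#' Simulate the CFR for a molecule at the TCP center
#'
#' Places the molecule at the origin with the central donut exposure on
#' top of it. With a perfect donut zero the center signal is
#' I_center = 0; the outer exposures see the donut flank,
#' I_i = h_eff,i(0,0,0). Background per exposure follows
#' [background_intensity()]. Outer means are dwell-weighted, and
#' CFR = (B_center + I_center) / (B_outer_mean + I_outer_mean).
#'
#' @param cfg an [optical_config()].
#' @param tcp an [tcp_pattern()].
#' @param c_imager imager concentration, nM.
#' @param zero_floor imperfect-null floor: additive excitation intensity
#'   at the donut center as a fraction of the donut peak (default 0,
#'   a perfect zero).
#' @param exc,det optional precomputed PSFs (reused across sweeps).
#' @return list of class `mfx_cfr_scenario` with `cfr`, per-exposure `B`
#'   and `I`, the center/outer aggregates and the inputs.
#' @export
simulate_cfr <- function(cfg, tcp, c_imager, zero_floor = 0,
                         exc = NULL, det = NULL) {
  if (is.null(exc)) exc <- excitation_donut(cfg)
  if (is.null(det)) det <- detection_psf(cfg)
  tab <- attr(exc, "radial")
  n_exp <- nrow(tcp$positions)
  i0 <- (length(det$x) + 1) %/% 2
  det0 <- det$values[i0, i0, i0]
  exc_at <- function(r) {
    stats::approx(tab$r, tab$I[, i0], xout = r, rule = 2)$y + zero_floor
  }
  B <- numeric(n_exp)
  I <- numeric(n_exp)
  for (i in seq_len(n_exp)) {
    pos <- tcp$positions[i, ]
    h_eff <- effective_psf(exc, det, pos)
    if (zero_floor > 0) {
      h_eff$values <- h_eff$values + zero_floor * det$values
    }
    B[i] <- background_intensity(h_eff, c_imager)
    I[i] <- exc_at(sqrt(sum(pos^2))) * det0
  }
  w_out <- tcp$dwell[-1] / sum(tcp$dwell[-1])
  B_outer <- sum(w_out * B[-1])
  I_outer <- sum(w_out * I[-1])
  denom <- B_outer + I_outer
  cfr <- if (denom > 0) (B[1] + I[1]) / denom else NA_real_
  structure(list(cfr = cfr, B = B, I = I,
                 B_center = B[1], I_center = I[1],
                 B_outer_mean = B_outer, I_outer_mean = I_outer,
                 c_imager = c_imager, L = tcp$L,
                 pinhole_au = cfg$pinhole_au, zero_floor = zero_floor),
            class = "mfx_cfr_scenario")
}

#' Sweep the CFR over concentration, pinhole size and TCP diameter
#'
#' @param cfg base [optical_config()] (its pinhole is replaced by the
#'   sweep values).
#' @param concentrations imager concentrations, nM.
#' @param pinholes_au pinhole diameters, AU.
#' @param L_values TCP diameters, nm.
#' @param ... passed to [simulate_cfr()].
#' @return data.frame with one row per (c, pinhole, L) combination and
#'   columns `c_imager`, `pinhole_au`, `L`, `cfr`, `B_center`,
#'   `B_outer_mean`, `I_outer_mean`.
#' @export
cfr_sweep <- function(cfg, concentrations, pinholes_au = cfg$pinhole_au,
                      L_values = 40, ...) {
  exc <- excitation_donut(cfg)
  rows <- list()
  for (ph in pinholes_au) {
    cfg_ph <- cfg
    cfg_ph$pinhole_au <- ph
    det <- detection_psf(cfg_ph)
    for (L in L_values) {
      pat <- tcp_pattern(L)
      for (cc in concentrations) {
        s <- simulate_cfr(cfg_ph, pat, cc, exc = exc, det = det, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          c_imager = cc, pinhole_au = ph, L = L, cfr = s$cfr,
          B_center = s$B_center, B_outer_mean = s$B_outer_mean,
          I_outer_mean = s$I_outer_mean)
      }
    }
  }
  do.call(rbind, rows)
}
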