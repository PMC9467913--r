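# scalar vortex focal intensity, computed independently of the package's
# vectorial machinery: |int sqrt(cos t) sin t J1(k r sin t) dt|^2
scalar_vortex_profile <- function(r, lambda, na, n_imm) {
  k <- 2 * pi * n_imm / lambda
  alpha <- asin(na / n_imm)
  vapply(r, function(ri) {
    f <- function(t) sqrt(cos(t)) * sin(t) * besselJ(k * ri * sin(t), 1)
    stats::integrate(f, 0, alpha, rel.tol = 1e-9)$value^2
  }, numeric(1))
}

test_that("the donut excitation has an exact on-axis null and a ring focus", {
  ox <- optics_coarse()
  exc <- ox$exc
  i0 <- (length(exc$x) + 1) %/% 2
  peak <- max(exc$values)
  expect_lte(exc$values[i0, i0, i0] / peak, 1e-3)
  # the null runs along the whole optical axis for a charge-1 vortex
  expect_true(all(exc$values[i0, i0, ] / peak <= 1e-3))
  expect_true(all(exc$values >= 0))
  # rotational symmetry of the focal-plane slice
  slice <- exc$values[, , i0]
  expect_equal(slice, t(slice), tolerance = 1e-9)
  expect_equal(slice, slice[rev(seq_len(nrow(slice))), ], tolerance = 1e-9)
  # ring radius against the independent scalar vortex model
  r <- seq(0, 600, by = 5)
  scal <- scalar_vortex_profile(r, ox$cfg$lambda_exc, ox$cfg$na,
                                ox$cfg$n_immersion)
  r_scal <- r[which.max(scal)]
  prof <- slice[i0:nrow(slice), i0]
  r_vec <- exc$x[i0:length(exc$x)][which.max(prof)]
  expect_lt(abs(r_vec - r_scal) / r_scal, 0.2)
})

test_that("a coarse grid triggers the sampling warning", {
  expect_warning(optical_config(grid_spacing = 80), "coarse")
})

test_that("the detection PSF peaks on axis and broadens monotonically with the pinhole", {
  ox <- optics_coarse()
  det <- ox$det
  i0 <- (length(det$x) + 1) %/% 2
  expect_equal(which.max(det$values),
               (i0 - 1) * length(det$x)^2 + (i0 - 1) * length(det$x) + i0)
  expect_true(all(det$values >= 0))
  # off-axis/on-axis ratio never decreases as the pinhole opens
  ratios <- vapply(c(0.3, 0.6, 1.2, 2.4), function(ph) {
    cfg <- ox$cfg
    cfg$pinhole_au <- ph
    d <- detection_psf(cfg)
    ir <- i0 + 8  # 320 nm off axis at the 40 nm test grid
    d$values[ir, i0, i0] / d$values[i0, i0, i0]
  }, numeric(1))
  expect_true(all(diff(ratios) > -1e-9))
  # very large pinhole approaches laterally flat (widefield) detection
  expect_gt(ratios[4] / ratios[1], 2)
})

test_that("the effective PSF is the product of shifted excitation and centered detection", {
  ox <- optics_coarse()
  h0 <- effective_psf(ox$exc, ox$det, c(0, 0))
  expect_equal(h0$values, ox$exc$values * ox$det$values, tolerance = 1e-12)
  # product bound
  expect_true(all(h0$values <= pmin(ox$exc$values / max(ox$exc$values),
                                    ox$det$values) * max(ox$exc$values) +
                    1e-12))
  # shift bookkeeping: after shifting by one grid step d, the origin sees
  # the donut flank at radius |d|, and the exposure position sees the null
  d <- ox$cfg$grid_spacing
  hs <- effective_psf(ox$exc, ox$det, c(d, 0))
  i0 <- (length(ox$exc$x) + 1) %/% 2
  tab <- attr(ox$exc, "radial")
  exc_r <- approx(tab$r, tab$I[, i0], xout = d)$y
  expect_equal(hs$values[i0, i0, i0], exc_r * ox$det$values[i0, i0, i0],
               tolerance = 1e-9)
  expect_equal(hs$values[i0 + 1, i0, i0] /
                 ox$det$values[i0 + 1, i0, i0], 0, tolerance = 1e-12)
  expect_error(effective_psf(ox$exc, ox$det, c(1e4, 0)), "beyond")
})

test_that("background is linear in concentration and symmetric across outer exposures", {
  ox <- optics_coarse()
  pat <- tcp_pattern(40)
  h <- effective_psf(ox$exc, ox$det, pat$positions[2, ])
  expect_identical(background_intensity(h, 0), 0)
  b1 <- background_intensity(h, 1)
  expect_equal(background_intensity(h, 2), 2 * b1, tolerance = 1e-12)
  expect_equal(background_intensity(h, 7.5), 7.5 * b1, tolerance = 1e-12)
  s <- simulate_cfr(ox$cfg, pat, 2, exc = ox$exc, det = ox$det)
  b_out <- s$B[-1]
  expect_lt(diff(range(b_out)) / mean(b_out), 0.05)
})

test_that("CFR vanishes for a perfect zero without background and grows with c and pinhole", {
  ox <- optics_coarse()
  pat <- tcp_pattern(40)
  s0 <- simulate_cfr(ox$cfg, pat, 0, exc = ox$exc, det = ox$det)
  expect_identical(s0$I_center, 0)
  expect_identical(s0$cfr, 0)
  sweep_c <- cfr_sweep(ox$cfg, concentrations = c(0.5, 1, 2, 4))
  expect_true(all(diff(sweep_c$cfr) > 0))
  sweep_ph <- vapply(c(0.4, 0.8, 1.6), function(ph) {
    cfg <- ox$cfg
    cfg$pinhole_au <- ph
    simulate_cfr(cfg, pat, 2, exc = ox$exc)$cfr
  }, numeric(1))
  expect_true(all(diff(sweep_ph) > 0))
  # an imperfect null lifts the center signal and the CFR
  s_eps <- simulate_cfr(ox$cfg, pat, 2, zero_floor = 0.01,
                        exc = ox$exc, det = ox$det)
  expect_gt(s_eps$I_center, 0)
  expect_gt(s_eps$cfr, simulate_cfr(ox$cfg, pat, 2, exc = ox$exc,
                                    det = ox$det)$cfr)
})

test_that("the simulated CFR is stable under grid refinement", {
  cfg_coarse <- optical_config(grid_spacing = 40, grid_halfwidth = 1000,
                               quad_nodes = 64)
  cfg_fine <- optical_config(grid_spacing = 20, grid_halfwidth = 1000,
                             quad_nodes = 64)
  pat <- tcp_pattern(40)
  cfr_c <- simulate_cfr(cfg_coarse, pat, 2)$cfr
  cfr_f <- simulate_cfr(cfg_fine, pat, 2)$cfr
  expect_lt(abs(cfr_f - cfr_c) / cfr_f, 0.05)
})
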