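test_that("event sigma_r implements the RMS of the coordinate SDs", {
  # s_x = 3, s_y = 4 -> sqrt((9 + 16)/2)
  x <- c(-1, 0, 1) * 3
  y <- c(-1, 0, 1) * 4
  locs <- data.frame(x = x / sd(x) * 3, y = y / sd(y) * 4,
                     z = 0, tid = 1L)
  locs <- rbind(locs, locs[1, ], locs[2, ])  # n = 5 for eligibility
  sx <- sd(locs$x); sy <- sd(locs$y)
  expect_equal(event_sigma_r(locs), sqrt((sx^2 + sy^2) / 2))
  # isotropy: s_x = s_y = s  ->  sigma_r = s
  iso <- data.frame(x = c(-2, -1, 0, 1, 2), y = c(0, 1, -1, 2, -2))
  iso$y <- iso$y / sd(iso$y) * sd(iso$x)
  expect_equal(event_sigma_r(iso), sd(iso$x))
  # fewer than five localizations: sentinel, not an error
  expect_true(is.na(event_sigma_r(iso[1:4, ])))
})

test_that("sigma_r is invariant under focal-plane rotation", {
  set.seed(8)
  locs <- data.frame(x = rnorm(40, sd = 2), y = rnorm(40, sd = 2))
  s0 <- event_sigma_r(locs)
  for (phi in c(0.3, pi / 4, 1.8)) {
    rot <- data.frame(x = cos(phi) * locs$x - sin(phi) * locs$y,
                      y = sin(phi) * locs$x + cos(phi) * locs$y)
    # exact for isotropic scatter in expectation; numerically the trace of
    # the covariance is rotation invariant for any sample
    expect_equal(event_sigma_r(rot), s0, tolerance = 1e-10)
  }
})

test_that("dataset sigma is the median over eligible events", {
  mk_ev <- function(sigmas, n = 9) {
    locs <- do.call(rbind, lapply(seq_along(sigmas), function(i) {
      v <- scale(rnorm(n))[, 1]
      data.frame(tid = i, x = v * sigmas[i], y = v * sigmas[i], z = 0,
                 tim = i)
    }))
    ev <- data.frame(tid = seq_along(sigmas), t_start = seq_along(sigmas),
                     t_end = seq_along(sigmas), n = n,
                     x = 0, y = 0)
    structure(ev, locs = locs, class = c("mfx_events", "data.frame"))
  }
  set.seed(1)
  ev <- mk_ev(c(2, 3, 9))
  expect_equal(dataset_sigma(ev), 3, tolerance = 1e-10)
  ev1 <- mk_ev(5)
  expect_equal(dataset_sigma(ev1), 5, tolerance = 1e-10)
})

test_that("combined sigma is the n-occurrence-weighted average of <sigma>/sqrt(n)", {
  mk <- function(ns, sigma = 2) {
    locs <- do.call(rbind, lapply(seq_along(ns), function(i) {
      v <- scale(rnorm(ns[i]))[, 1]
      data.frame(tid = i, x = v * sigma, y = v * sigma, tim = i)
    }))
    ev <- data.frame(tid = seq_along(ns), t_start = seq_along(ns),
                     t_end = seq_along(ns), n = ns, x = 0, y = 0)
    structure(ev, locs = locs, class = c("mfx_events", "data.frame"))
  }
  set.seed(2)
  # all events n = 4 fails eligibility at the default threshold; lower it
  ev4 <- mk(c(4, 4, 4))
  expect_equal(combined_sigma(ev4, min_locs = 4), 2 / sqrt(4) * 1,
               tolerance = 1e-10)
  # single event, n = 9, sigma_r = 3
  ev9 <- mk(9, sigma = 3)
  expect_equal(combined_sigma(ev9), 1, tolerance = 1e-10)
  # hand evaluation: n in {4, 16}, <sigma> = 2 -> 2*(1/2 + 1/4)/2 = 0.75
  ev416 <- mk(c(4, 16))
  expect_equal(combined_sigma(ev416, min_locs = 4), 0.75, tolerance = 1e-10)
  # per-event variant agrees here because sigma is identical across events
  expect_equal(combined_sigma(ev416, min_locs = 4, method = "per_event"),
               0.75, tolerance = 1e-10)
})

test_that("combined sigma decreases when every event gains localizations", {
  fx <- sim_basic()
  ev <- fx$events
  src <- combined_sigma(ev)
  sr <- dataset_sigma(ev)
  expect_lt(src, sr)
  # multiplying every n by k > 1 shrinks the combined precision
  locs <- attr(ev, "locs")
  ev2 <- ev
  attr(ev2, "locs") <- locs
  es <- vapply(ev$tid, function(id) sum(locs$tid == id), numeric(1))
  # analytic check on the pooled formula with a scaled n histogram
  msig <- mean(vapply(ev$tid[es >= 5], function(id) {
    l <- locs[locs$tid == id, ]
    event_sigma_r(l)
  }, numeric(1)), na.rm = TRUE)
  w <- es[es >= 5]
  expect_equal(src, msig * mean(1 / sqrt(w)), tolerance = 1e-10)
  expect_lt(msig * mean(1 / sqrt(4 * w)), src)
})

test_that("precision summary recovers the generator noise", {
  fx <- sim_basic()
  p <- precision_summary(fx$events)
  expect_equal(p$sigma_r, fx$config$sigma_true, tolerance = 0.1)
  expect_lt(p$sigma_rc, p$sigma_r)
  expect_true(is.na(p$sigma_z))  # 2D dataset
  expect_identical(sum(p$n_histogram), p$n_events_used)
})

test_that("3D datasets yield z precisions with sigma_zc < sigma_z", {
  st <- make_structure("random", list(n_sites = 40, extent = 400),
                       ndim = 3, seed = 3)
  cfg <- acquisition_config(c_imager = 2, duration = 1500, sigma_true = 3)
  sim <- simulate_acquisition(st, cfg, seed = 21)
  p <- precision_summary(extract_events(sim$dataset))
  expect_equal(p$sigma_z, cfg$sigma_true, tolerance = 0.15)
  expect_lt(p$sigma_zc, p$sigma_z)
})
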