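test_that("window arithmetic covers all events with the stated overlap", {
  ev <- data.frame(t_start = seq_len(6000))
  w <- window_events(ev, target_per_window = 2000, overlap_fraction = 0.5)
  expect_length(w, 5L)
  expect_true(all(lengths(w) == 2000L))
  expect_setequal(sort(unique(unlist(w))), seq_len(6000))
  # consecutive windows share half their events
  expect_length(intersect(w[[1]], w[[2]]), 1000L)
  # too few events: a single window, and the estimator refuses
  expect_warning(w1 <- window_events(data.frame(t_start = 1:2000)),
                 "too few")
  expect_length(w1, 1L)
  ev_small <- sim_basic()$events
  expect_error(suppressWarnings(
    estimate_drift(ev_small, target_per_window = 1e6)), "two windows")
})

test_that("Gaussian rendering conserves mass and commutes with translation", {
  set.seed(4)
  pos <- matrix(runif(400, 0, 200), ncol = 2)
  img <- render_positions(pos, sigma = 2, pixel = 1)
  expect_equal(sum(img$values), nrow(pos), tolerance = 1e-9)
  expect_true(all(img$values > -1e-12))
  # single position: blob peaks at the nearest pixel
  one <- render_positions(matrix(c(50.2, 70.8), 1), sigma = 2, pixel = 1,
                          bounds = rbind(c(40, 60), c(60, 80)))
  peak <- arrayInd(which.max(one$values), dim(one$values))
  peak_nm <- one$origin + (peak - 1) * one$pixel
  expect_lt(max(abs(peak_nm - c(50.2, 70.8))), one$pixel)
  # shift theorem: translated copies give translated images
  bounds <- rbind(c(-20, -20), c(240, 240))
  a <- render_positions(pos, sigma = 2, pixel = 1, bounds = bounds)
  b <- render_positions(sweep(pos, 2, c(10, 4), "+"), sigma = 2,
                        pixel = 1, bounds = bounds)
  shifted <- a$values * 0
  shifted[11:260, 5:260] <- a$values[1:250, 1:256]
  expect_equal(b$values[12:259, 6:259], shifted[12:259, 6:259],
               tolerance = 1e-6)
})

test_that("pairwise shifts are recovered to sub-pixel accuracy and antisymmetric", {
  set.seed(5)
  pos <- matrix(runif(1200, 0, 300), ncol = 2)
  bounds <- rbind(c(-30, -30), c(330, 330))
  a <- render_positions(pos, sigma = 2, pixel = 1, bounds = bounds)
  s_self <- pairwise_shift(a, a)
  expect_equal(s_self$shift, c(0, 0), tolerance = 1e-9)
  expect_true(s_self$ok)
  b <- render_positions(sweep(pos, 2, c(10, -4), "+"), sigma = 2,
                        pixel = 1, bounds = bounds)
  s <- pairwise_shift(a, b)
  expect_lt(max(abs(s$shift - c(10, -4))), 0.5)
  s_rev <- pairwise_shift(b, a)
  expect_lt(max(abs(s$shift + s_rev$shift)), 0.2)
  # featureless images are flagged unusable
  flat <- a; flat$values[] <- 1
  expect_false(pairwise_shift(flat, flat)$ok)
})

test_that("the least-squares solve reproduces consistent shifts exactly", {
  times <- c(0, 10, 20, 30)
  true_off <- cbind(c(0, 3, 6, 9), c(0, -2, -4, -6))
  pairs <- t(combn(4, 2))
  shifts <- data.frame(i = pairs[, 1], j = pairs[, 2],
                       dx = true_off[pairs[, 2], 1] - true_off[pairs[, 1], 1],
                       dy = true_off[pairs[, 2], 2] - true_off[pairs[, 1], 2],
                       ok = TRUE)
  tr <- solve_drift(shifts, times)
  centered <- sweep(true_off, 2, colMeans(true_off))
  expect_equal(tr$offsets, centered, tolerance = 1e-9)
  expect_equal(colMeans(tr$offsets), c(0, 0), tolerance = 1e-9)
  # linear trace: spline reproduces the line between knots
  expect_equal(eval_drift_trace(tr, 15)[1, ], centered[2, ] +
                 (centered[3, ] - centered[2, ]) / 2, tolerance = 1e-6)
  # all shifts zero -> zero trace; time translation leaves offsets alone
  z <- shifts; z$dx <- 0; z$dy <- 0
  expect_equal(solve_drift(z, times)$offsets, true_off * 0,
               tolerance = 1e-12)
  expect_equal(solve_drift(shifts, times + 500)$offsets, tr$offsets,
               tolerance = 1e-12)
  # disconnected graphs are refused with the missing windows named
  expect_error(solve_drift(shifts[shifts$i == 1 & shifts$j == 2, ],
                           times), "connect")
})

test_that("injected drift is recovered and corrected on the fixture", {
  for (kind in c("linear", "spline_random_walk")) {
    case <- drift_case(kind)
    expect_gte(length(case$trace$times), 10L)
    truth <- case$sim$truth$drift(case$trace$times)
    expect_lt(drift_rms(case$trace$offsets, truth), 2)
    corr <- correct_drift(case$events, case$trace)
    # corrected scatter about each site is tighter than uncorrected
    p_pre <- precision_summary(case$events)
    p_post <- precision_summary(corr)
    expect_lte(p_post$sigma_r, p_pre$sigma_r + 1e-9)
  }
})

test_that("zero trace is the identity and correction is near-idempotent", {
  case <- drift_case("spline_random_walk")
  ev <- case$events
  zero <- solve_drift(data.frame(i = 1, j = 2, dx = 0, dy = 0, ok = TRUE),
                      range(ev$t_start))
  same <- correct_drift(ev, zero)
  expect_equal(same$x, ev$x, tolerance = 1e-12)
  expect_equal(same$y, ev$y, tolerance = 1e-12)
  corr <- correct_drift(ev, case$trace)
  trace2 <- estimate_drift(corr, target_per_window = 250, pixel = 2)
  amp1 <- max(abs(sweep(case$trace$offsets, 2,
                        colMeans(case$trace$offsets))))
  amp2 <- max(abs(sweep(trace2$offsets, 2, colMeans(trace2$offsets))))
  expect_lt(amp2, 0.1 * amp1)
})

test_that("the estimated trace is invariant under a global position offset", {
  case <- drift_case("linear")
  ev <- case$events
  ev2 <- ev
  ev2$x <- ev2$x + 123.4
  ev2$y <- ev2$y - 56.7
  attr(ev2, "locs") <- attr(ev, "locs")
  trace2 <- estimate_drift(ev2, target_per_window = 250, pixel = 2)
  expect_equal(trace2$offsets, case$trace$offsets, tolerance = 1e-6)
})
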