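# Synthetic MINFLUX-export generator with known ground truth.
#
# Emulates the export layer of a DNA-PAINT MINFLUX acquisition: stochastic
# binding events per docking site (Poisson arrivals at rate k_on * c),
# bursts of repeated final-iteration localizations per trace ID with
# Gaussian localization noise, terminal non-valid attempts that delimit
# each event, a background-frequency column, and a smooth sample-drift
# trajectory. Photon counts and the on-line position estimator are not
# modeled; the generator produces what the instrument would have exported.

#' Build a synthetic labeling structure
#'
#' @param kind one of `"grid"` (rectangular lattice of sites),
#'   `"ring_array"` (rings of `corners` sites, ring centers on a lattice,
#'   loosely evoking nuclear-pore-like arrangements), `"filament"` (sites
#'   along a straight line) or `"random"` (uniform in a square).
#' @param params named list of kind-specific parameters:
#'   * grid: `nx`, `ny` (default 3), `spacing` (nm, default 50)
#'   * ring_array: `n_rings_x`, `n_rings_y` (default 2), `ring_spacing`
#'     (default 200 nm), `diameter` (default 100 nm), `corners` (default 8)
#'   * filament: `n_sites` (default 40), `pitch` (site spacing along the
#'     line, default 10 nm), `angle` (radians, default 0.3)
#'   * random: `n_sites` (default 50), `extent` (side of square, nm,
#'     default 500)
#'   Defaults are synthetic conveniences, not measured biology.
#' @param ndim 2 or 3; 3D structures get z = 0 except `"random"`, which
#'   spreads z uniformly over `params$z_extent` (default 200 nm).
#' @param seed RNG seed used by the `"random"` kind.
#' @return `mfx_structure`: list with `kind`, `sites` (matrix, one row per
#'   docking site, columns x/y[/z] in nm) and `params`.
#' @export
make_structure <- function(kind = c("grid", "ring_array", "filament", "random"),
                           params = list(), ndim = 2, seed = 1) {
  kind <- match.arg(kind)
  p <- params
  sites <- switch(kind,
    grid = {
      nx <- p$nx %||% 3L; ny <- p$ny %||% 3L; sp <- p$spacing %||% 50
      g <- expand.grid(x = (seq_len(nx) - (nx + 1) / 2) * sp,
                       y = (seq_len(ny) - (ny + 1) / 2) * sp)
      as.matrix(g)
    },
    ring_array = {
      nrx <- p$n_rings_x %||% 2L; nry <- p$n_rings_y %||% 2L
      rsp <- p$ring_spacing %||% 200; diam <- p$diameter %||% 100
      corners <- p$corners %||% 8L
      centers <- expand.grid(
        x = (seq_len(nrx) - (nrx + 1) / 2) * rsp,
        y = (seq_len(nry) - (nry + 1) / 2) * rsp)
      phi <- 2 * pi * (seq_len(corners) - 1) / corners
      do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        cbind(x = centers$x[i] + diam / 2 * cos(phi),
              y = centers$y[i] + diam / 2 * sin(phi))
      }))
    },
    filament = {
      n <- p$n_sites %||% 40L; pitch <- p$pitch %||% 10
      ang <- p$angle %||% 0.3
      s <- (seq_len(n) - (n + 1) / 2) * pitch
      cbind(x = s * cos(ang), y = s * sin(ang))
    },
    random = {
      set.seed(seed)
      n <- p$n_sites %||% 50L; ext <- p$extent %||% 500
      cbind(x = stats::runif(n, -ext / 2, ext / 2),
            y = stats::runif(n, -ext / 2, ext / 2))
    }
  )
  ndim <- as.integer(ndim)
  stopifnot(ndim %in% c(2L, 3L))
  if (ndim == 3L) {
    z <- if (kind == "random") {
      zext <- p$z_extent %||% 200
      stats::runif(nrow(sites), -zext / 2, zext / 2)
    } else rep(0, nrow(sites))
    sites <- cbind(sites, z = z)
  }
  stopifnot(nrow(sites) >= 1L, all(is.finite(sites)))
  structure(list(kind = kind, sites = sites, params = p, ndim = ndim),
            class = "mfx_structure")
}

#' Acquisition parameters for the synthetic generator
#'
#' Defaults are plausible DNA-PAINT MINFLUX settings chosen as test
#' conditions: a per-site on-rate constant of 1e-3 events/s/nM (about
#' 1e6 /M/s), 2 nM imager, mean bound time 0.4 s, 50 final-iteration
#' localizations per second while bound, 2 nm isotropic localization noise
#' and a 20 kHz background frequency.
#'
#' @param c_imager imager concentration, nM.
#' @param k_on per-site binding rate constant, events/s/nM.
#' @param mean_event_duration mean bound-state duration, s.
#' @param loc_rate valid localizations per second during an event, Hz.
#' @param sigma_true per-axis localization noise SD, nm.
#' @param n_invalid_tail terminal non-valid attempts appended per event.
#' @param fbg_true background emission frequency, Hz.
#' @param duration total acquisition time, s.
#' @param false_event_rate spurious (unbound) events per second.
#' @param cfr_median,cfr_sdlog lognormal CFR model for valid records
#'   (median and log-SD); a sampling convenience, not an optics model —
#'   physical CFR values come from [simulate_cfr()].
#' @return list of class `mfx_acq_config`.
#' @export
acquisition_config <- function(c_imager = 2, k_on = 1e-3,
                               mean_event_duration = 0.4, loc_rate = 50,
                               sigma_true = 2, n_invalid_tail = 3,
                               fbg_true = 2e4, duration = 600,
                               false_event_rate = 0,
                               cfr_median = 0.4, cfr_sdlog = 0.3) {
  cfg <- list(c_imager = c_imager, k_on = k_on,
              mean_event_duration = mean_event_duration,
              loc_rate = loc_rate, sigma_true = sigma_true,
              n_invalid_tail = as.integer(n_invalid_tail),
              fbg_true = fbg_true, duration = duration,
              false_event_rate = false_event_rate,
              cfr_median = cfr_median, cfr_sdlog = cfr_sdlog)
  rates <- unlist(cfg[c("c_imager", "k_on", "loc_rate", "fbg_true",
                        "false_event_rate")])
  if (any(rates < 0)) stop("rates must be >= 0")
  if (cfg$sigma_true <= 0) stop("sigma_true must be > 0")
  if (cfg$duration <= 0) stop("duration must be > 0")
  class(cfg) <- "mfx_acq_config"
  cfg
}

#' Sample-drift model for the synthetic generator
#'
#' @param kind `"none"`, `"linear"` (constant velocity) or
#'   `"spline_random_walk"` (Gaussian increments at regular knots, joined
#'   by a natural cubic spline). All trajectories start at zero offset.
#' @param velocity per-axis drift velocity, nm/s (linear kind; recycled).
#' @param knot_spacing knot spacing, s (random-walk kind).
#' @param step_sd per-knot increment SD, nm (random-walk kind).
#' @param seed RNG seed for the random-walk realization.
#' @return list of class `mfx_drift_model`.
#' @export
drift_model <- function(kind = c("none", "linear", "spline_random_walk"),
                        velocity = 0, knot_spacing = 60, step_sd = 3,
                        seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, velocity = velocity,
                 knot_spacing = knot_spacing, step_sd = step_sd,
                 seed = seed),
            class = "mfx_drift_model")
}

#' Realize a drift model as a vectorized trajectory function
#'
#' @param model an [drift_model()] object.
#' @param duration acquisition span, s.
#' @param ndim 2 or 3.
#' @return function(t) returning an `length(t) x ndim` matrix of offsets in
#'   nm, with offset 0 at t = 0.
#' @export
realize_drift <- function(model, duration, ndim = 2) {
  ndim <- as.integer(ndim)
  switch(model$kind,
    none = function(t) matrix(0, length(t), ndim),
    linear = {
      v <- rep_len(model$velocity, ndim)
      function(t) outer(t, v)
    },
    spline_random_walk = {
      knots <- seq(0, duration + model$knot_spacing,
                   by = model$knot_spacing)
      set.seed(model$seed)
      steps <- matrix(stats::rnorm((length(knots) - 1L) * ndim,
                                   sd = model$step_sd),
                      ncol = ndim)
      offsets <- rbind(0, apply(steps, 2, cumsum))
      funs <- lapply(seq_len(ndim), function(a) {
        stats::splinefun(knots, offsets[, a], method = "natural")
      })
      function(t) {
        matrix(unlist(lapply(funs, function(f) f(t))), length(t), ndim)
      }
    }
  )
}

#' Expected mean time between binding events
#'
#' Closed-form waiting time of the merged binding process: with N sites
#' each binding imager at rate `k_on * c_imager`, inter-event gaps are
#' approximately exponential with rate `k_on * c_imager * N` (exact in the
#' limit of short bound times). The mean gap is `1 / rate`; because the
#' dataset statistic t_btw is a *median* of gaps, its expectation is
#' `log(2) / rate`.
#'
#' @param config an [acquisition_config()].
#' @param structure an [make_structure()] object (supplies the site count).
#' @param statistic `"mean"` for the mean gap, `"median"` for the expected
#'   median gap matching [time_between_events()].
#' @return expected gap in seconds; `Inf` when the binding rate is zero.
#' @export
expected_t_btw <- function(config, structure,
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  rate <- config$k_on * config$c_imager * nrow(structure$sites)
  if (rate <= 0) return(Inf)
  if (statistic == "mean") 1 / rate else log(2) / rate
}

#' Simulate a DNA-PAINT MINFLUX acquisition
#'
#' Per docking site, binding events arrive as a Poisson process with rate
#' `k_on * c_imager` and exponential bound times (a site cannot rebind
#' while occupied, so successive events at one site never overlap). While
#' bound, valid final-iteration localizations are emitted on a fixed duty
#' cycle of `1/loc_rate` seconds at the drifted site position plus
#' isotropic Gaussian noise `sigma_true`; one valid row per earlier
#' iteration (prelocalization to final-1, with proportionally coarser
#' noise) precedes them, and `n_invalid_tail` non-valid rows with NA
#' positions follow, the first of which defines the event end time.
#'
#' @param structure an [make_structure()] object.
#' @param config an [acquisition_config()].
#' @param drift an [drift_model()]; default no drift.
#' @param seed RNG seed; identical seeds give identical output.
#' @param final_iteration index of the last iteration (4 for 2D, 9 for 3D
#'   by default).
#' @return list with `dataset` (an [mfx_dataset]) and `truth`, a list with
#'   `events` (data.frame: tid, site, true position, t_start, t_end, n),
#'   `drift` (function of time, as [realize_drift()]) and `config` echo.
#' @export
simulate_acquisition <- function(structure, config,
                                 drift = drift_model("none"), seed = 1,
                                 final_iteration = NULL) {
  stopifnot(inherits(structure, "mfx_structure"),
            inherits(config, "mfx_acq_config"))
  ndim <- structure$ndim
  if (is.null(final_iteration)) {
    final_iteration <- if (ndim == 2L) 4L else 9L
  }
  n_sites <- nrow(structure$sites)
  if (n_sites == 0L) stop("structure has no sites")
  drift_fn <- realize_drift(drift, config$duration, ndim)

  set.seed(seed)
  rate <- config$k_on * config$c_imager
  events <- list()
  if (rate > 0) {
    for (s in seq_len(n_sites)) {
      t <- 0
      repeat {
        t_start <- t + stats::rexp(1, rate)
        if (t_start > config$duration) break
        dur <- stats::rexp(1, 1 / config$mean_event_duration)
        events[[length(events) + 1L]] <-
          c(site = s, start = t_start,
            end = min(t_start + dur, config$duration))
        t <- t_start + dur
      }
    }
  }
  if (config$false_event_rate > 0) {
    n_false <- stats::rpois(1, config$false_event_rate * config$duration)
    for (i in seq_len(n_false)) {
      t_start <- stats::runif(1, 0, config$duration)
      events[[length(events) + 1L]] <-
        c(site = NA_real_, start = t_start,
          end = min(t_start + stats::rexp(1, config$loc_rate),
                    config$duration))
    }
  }
  axis_names <- c("x", "y", "z")[seq_len(ndim)]
  if (length(events) == 0L) {
    empty <- as.data.frame(matrix(numeric(0), 0, 6 + ndim + 3))
    names(empty) <- c("tid", "tim", "vld", "itr", axis_names,
                      "efo", "fbg", "cfr")
    ds <- mfx_dataset(empty, ndim = ndim, final_iteration = final_iteration)
    truth_events <- data.frame(tid = integer(0), site = integer(0),
                               t_start = numeric(0), t_end = numeric(0),
                               n = integer(0))
    return(list(dataset = ds,
                truth = list(events = truth_events, drift = drift_fn,
                             config = config, seed = seed)))
  }
  ev <- as.data.frame(do.call(rbind, events))
  ev <- ev[order(ev$start), , drop = FALSE]
  ev$tid <- seq_len(nrow(ev))
  dt <- 1 / config$loc_rate
  # false events have no docking site; draw their position once up front
  ev_pos <- t(vapply(seq_len(nrow(ev)), function(i) {
    if (!is.na(ev$site[i])) as.numeric(structure$sites[ev$site[i], ])
    else stats::runif(ndim, -200, 200)
  }, numeric(ndim)))
  rec_list <- vector("list", nrow(ev))
  truth_list <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    start <- ev$start[i]; end <- ev$end[i]
    pos0 <- ev_pos[i, ]
    t_valid <- seq(start, max(start, end), by = dt)
    n <- length(t_valid)
    # zoom-in iterations just before the burst, coarser by iteration
    itr_pre <- seq_len(final_iteration) - 1L
    t_pre <- start - rev(seq_along(itr_pre)) * dt / 10
    t_pre <- pmax(t_pre, 0)
    sigma_pre <- config$sigma_true * 2^(final_iteration - itr_pre)
    t_invalid <- if (config$n_invalid_tail > 0) {
      t_valid[n] + seq_len(config$n_invalid_tail) * dt
    } else numeric(0)
    tims <- c(t_pre, t_valid, t_invalid)
    itrs <- c(itr_pre, rep(final_iteration, n + length(t_invalid)))
    vlds <- c(rep(TRUE, length(t_pre) + n), rep(FALSE, length(t_invalid)))
    sig <- c(sigma_pre, rep(config$sigma_true, n))
    n_loc <- length(t_pre) + n
    pos <- matrix(rep(pos0, each = n_loc), n_loc, ndim) +
      drift_fn(tims[seq_len(n_loc)]) +
      matrix(stats::rnorm(n_loc * ndim), n_loc, ndim) * sig
    pos <- rbind(pos, matrix(NA_real_, length(t_invalid), ndim))
    rec <- data.frame(tid = ev$tid[i], tim = tims, vld = vlds, itr = itrs)
    for (a in seq_len(ndim)) rec[[axis_names[a]]] <- pos[, a]
    rec$efo <- ifelse(vlds, stats::rlnorm(nrow(rec), log(1e5), 0.2),
                      NA_real_)
    rec$fbg <- pmax(0, config$fbg_true *
                      (1 + stats::rnorm(nrow(rec), 0, 0.05)))
    rec$cfr <- ifelse(vlds & itrs == final_iteration,
                      stats::rlnorm(nrow(rec), log(config$cfr_median),
                                    config$cfr_sdlog),
                      NA_real_)
    rec_list[[i]] <- rec
    truth_list[[i]] <- data.frame(
      tid = ev$tid[i], site = ev$site[i],
      t_start = start,
      t_end = if (length(t_invalid) > 0) t_invalid[1] else t_valid[n],
      n = n)
  }
  records <- do.call(rbind, rec_list)
  truth_events <- do.call(rbind, truth_list)
  colnames(ev_pos) <- axis_names
  truth_events <- cbind(truth_events, ev_pos)
  ds <- mfx_dataset(records, ndim = ndim, final_iteration = final_iteration,
                    metadata = list(seed = seed,
                                    c_imager = config$c_imager,
                                    sigma_true = config$sigma_true))
  list(dataset = ds,
       truth = list(events = truth_events, drift = drift_fn,
                    config = config, seed = seed))
}
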