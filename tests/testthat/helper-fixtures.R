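# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Ten localization attempts, time stamps 1..10, four molecules with
# interleaved valid/non-valid rows. Molecules 1 and 3 never localize
# validly; molecule 2 is the first valid event (ending at TIM = 5, its
# first trailing non-valid attempt), molecule 4 the second (starting at
# TIM = 7).
toy_trace_dataset <- function() {
  rec <- data.frame(
    tid = c(1L, 2L, 2L, 2L, 2L, 3L, 4L, 4L, 4L, 4L),
    tim = 1:10,
    vld = c(0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),
    itr = 4L,
    x = c(NA, 10, 11, 9, NA, NA, 50, 51, NA, NA),
    y = c(NA, 20, 21, 19, NA, NA, 60, 61, NA, NA)
  )
  mfx_dataset(rec, ndim = 2, final_iteration = 4)
}

# moderate 2D acquisition: 60 random sites, 2 nM imager, no drift
sim_basic <- function() {
  fixture("sim_basic", {
    st <- make_structure("random", list(n_sites = 60, extent = 600),
                         seed = 2)
    cfg <- acquisition_config(c_imager = 2, k_on = 1e-3, duration = 2000,
                              sigma_true = 2, loc_rate = 50,
                              mean_event_duration = 0.4)
    sim <- simulate_acquisition(st, cfg, seed = 7)
    list(structure = st, config = cfg, sim = sim,
         events = extract_events(sim$dataset))
  })
}

# sparse-noise acquisition used for FRC: coarser single-localization
# precision so the combined-localization resolution sits above the
# rendering Nyquist limit
sim_frc <- function() {
  fixture("sim_frc", {
    st <- make_structure("random", list(n_sites = 150, extent = 800),
                         seed = 5)
    cfg <- acquisition_config(c_imager = 4, k_on = 1e-3, duration = 3000,
                              sigma_true = 5, loc_rate = 10,
                              mean_event_duration = 0.5)
    sim <- simulate_acquisition(st, cfg, seed = 11)
    list(structure = st, config = cfg, sim = sim,
         events = extract_events(sim$dataset))
  })
}

# drift-correction fixtures: same structure/kinetics as sim_frc, with an
# injected known drift; the estimated trace is cached alongside
drift_case <- function(kind) {
  fixture(paste0("drift_", kind), {
    st <- make_structure("random", list(n_sites = 150, extent = 800),
                         seed = 5)
    cfg <- acquisition_config(c_imager = 4, k_on = 1e-3, duration = 3000,
                              sigma_true = 5, loc_rate = 10,
                              mean_event_duration = 0.5)
    dm <- if (kind == "linear") {
      drift_model("linear", velocity = c(10, -6) / 3600)  # nm per hour
    } else {
      drift_model("spline_random_walk", knot_spacing = 300, step_sd = 8,
                  seed = 4)
    }
    sim <- simulate_acquisition(st, cfg, drift = dm,
                                seed = if (kind == "linear") 13 else 12)
    events <- extract_events(sim$dataset)
    trace <- estimate_drift(events, target_per_window = 250,
                            overlap_fraction = 0.5, pixel = 2)
    list(sim = sim, events = events, trace = trace)
  })
}

# gauge-free RMS disagreement between a recovered and a true drift curve
drift_rms <- function(offsets, truth) {
  resid <- offsets - truth
  resid <- sweep(resid, 2, colMeans(resid))
  sqrt(mean(resid^2))
}

# coarse optics shared by the CFR simulator tests
optics_coarse <- function() {
  fixture("optics_coarse", {
    cfg <- optical_config(grid_spacing = 40, grid_halfwidth = 1000,
                          quad_nodes = 64)
    list(cfg = cfg, exc = excitation_donut(cfg), det = detection_psf(cfg))
  })
}
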