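# minfluxr

Post-processing, quantification and simulation of **DNA-PAINT MINFLUX**
single-molecule localization data.

MINFLUX localizes single fluorophores by probing them with a donut-shaped
excitation beam whose targeted coordinate pattern (TCP) shrinks over
iterations down to `L = 40 nm`, reaching nanometer localization precision
with few photons. With DNA-PAINT labeling, dye-carrying imager strands
bind target-bound docking strands transiently, so the raw export is a time
series of localization *attempts*: bursts of valid localizations sharing a
trace ID (one binding event), terminated by non-valid attempts, embedded
in background. This package turns such exports into the standard
quantification parameters and provides the simulators needed to validate
every estimator without a microscope.

## What it computes

* **Event statistics** — binding events from trace IDs; the time between
  consecutive valid events `t_btw` (median over the first 100 events, the
  gap being `start(next) − end(previous)`); the median center-frequency
  ratio (CFR) and median background emission frequency `f_bg` of the
  valid last-iteration localizations.
* **Localization precision** — per event (≥ 5 localizations)
  `σ_r = sqrt((σ_x² + σ_y²)/2)`; the dataset precision is the median σ_r.
  The combined precision after averaging an event's *n* localizations is
  `σ_rc = ⟨⟨σ_r⟩/√n⟩_n`, the mean σ_r divided by √n and weighted by the
  occurrence of *n*; `σ_z`/`σ_zc` analogously in 3D.
* **Drift correction** — redundant cross-correlation: overlapping windows
  of ~2000 events, Gaussian renderings (σ = 2 nm), sub-pixel shifts for
  all window pairs from a Gaussian fit to the correlation peak, a
  least-squares drift curve through all pairwise constraints, cubic-spline
  interpolation subtracted from the coordinates.
* **FRC resolution** — Fourier ring correlation between histogram images
  of two random halves of the *combined* (per-event mean) localizations;
  resolution = inverse of the frequency where the curve drops below 1/7,
  averaged over repeated random splits.
* **CFR simulator** — vectorial (Richards–Wolf) focus fields: a
  circularly polarized charge-1 vortex donut at 642 nm, a confocal
  detection PSF at 680 nm integrated over the pinhole, effective PSFs
  `h_eff,i = h_exc,i · h_det` per TCP exposure, background
  `B_i = ∫ h_eff,i c dV`, signal `I_i = h_eff,i(0,0,0)`, and
  `CFR = (B_center + I_center) / ⟨B_outer + I_outer⟩`.
* **Rendering** — 2D count histograms (4 nm / 1 nm bins) and 3D Gaussian
  renderings (σ = 5 nm) with the axial scaling factor 0.7.
* **Synthetic data** — a generator emulating the export layer (Poisson
  binding kinetics per site, localization bursts with Gaussian noise,
  terminal non-valid attempts, background column, smooth drift) with a
  full ground-truth table.

## Worked example

```r
library(minfluxr)
st  <- make_structure("random", list(n_sites = 60, extent = 600), seed = 2)
cfg <- acquisition_config(c_imager = 2, sigma_true = 2, duration = 2000)
sim <- simulate_acquisition(st, cfg, seed = 7)
print(sim$dataset)
#> MINFLUX dataset: 6049 localization attempts (2D)
#>   final iteration 4; 4474 valid final-iteration localizations
#>   time span 15.120 .. 1998.516 s; 225 traces
ev <- extract_events(sim$dataset)
event_summary(sim$dataset)
#> events: 225 | t_btw 5.803 s | median CFR 0.3984 | median f_bg 2.003e+04 Hz
precision_summary(ev)
#> sigma_r  1.99 nm   sigma_rc 0.482 nm  (179 events)
expected_t_btw(cfg, st, "median")
#> [1] 5.776227
```

The 60 sites at 2 nM imager bind at a merged rate of 0.12 events/s, so
the median waiting time between events should be `log(2)/0.12 ≈ 5.78 s`;
the measured `t_btw` of 5.80 s recovers it. The injected 2 nm
localization noise is recovered as the median per-event precision
(1.99 nm), and averaging the ~20 localizations of a typical event brings
the combined precision σ_rc down to 0.48 nm.

The physical CFR simulator, for a molecule centered in a 40-nm TCP with a
perfect donut zero:

```r
cfg_opt <- optical_config()           # 642/680 nm, NA 1.4, 0.6 AU pinhole
s <- simulate_cfr(cfg_opt, tcp_pattern(40), c_imager = 2)
s$I_center   # 0    — the vortex null detects no on-axis emitter
s$cfr        # ~0.76 at 2 nM: background alone produces a sizable CFR
```

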