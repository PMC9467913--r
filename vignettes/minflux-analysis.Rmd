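---
title: "Quantifying DNA-PAINT MINFLUX acquisitions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-PAINT MINFLUX acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
data model, the estimators and their assumptions, the physical CFR
simulation, the numerical choices that were genuinely open, and the
limits of what the synthetic-data tests demonstrate.

## The data model

A MINFLUX acquisition exports one row per localization *attempt*:
a trace identifier `tid`, a time stamp `tim` (s), a validity flag `vld`,
the iteration index `itr` (0 is the prelocalization), the estimated
position `x, y[, z]` (nm), and optionally the effective emission
frequency `efo` (Hz), the background frequency `fbg` (Hz) and the
center-frequency ratio `cfr`. The instrument zooms in over iterations
(TCP diameter 288 → 151 → 76 → 40 nm in the default 2D sequence, see
`inst/extdata/seq-2d-default.json`); once a molecule survives to the last
iteration, the final two iterations repeat on a fixed duty cycle, so one
DNA-PAINT binding event appears as a burst of valid last-iteration rows
sharing a `tid`. The trace is closed by a predefined number of non-valid
attempts once the imager unbinds.

All quantification uses only valid last-iteration records (`vld = 1`,
`itr = 4` in 2D, `itr = 9` in 3D). Non-valid rows are retained because
they carry event end times.

Two conventions in this layer are ours rather than the instrument's:
the open CSV schema itself (the native export is proprietary), and the
encoding of terminal non-valid attempts as full rows with `vld = 0`,
NA positions and the event's `tid`. Positions are always nm, times s,
frequencies Hz.

## Events and acquisition statistics

An event starts at the time stamp of its first valid last-iteration
localization and ends at the first trailing non-valid attempt of the same
trace (falling back to the last valid stamp when the tail was not
exported — the terminating attempt count is instrument configuration we
cannot know). `t_btw` is the median, over the first 100 events, of
`start(next) − end(previous)` between consecutive events. With fewer than
100 events all are used; negative raw gaps — overlapping traces — are
clipped to zero with a warning rather than dropped, which keeps the
median defined while logging the anomaly for QC.

Because `t_btw` is a *median* of (approximately exponential) waiting
times, its expectation under the generator's kinetics is `log(2)/rate`,
not `1/rate`; `expected_t_btw()` exposes both so tests compare like with
like.

Median CFR and median `f_bg` are taken directly from the exported
columns of the valid last-iteration records. The package does not
re-derive `f_bg` from photon streams (the microscope estimates it between
events), and does not emulate the CFR-based filtering applied on-line in
early iterations — that behavior shapes the recorded data and cannot be
undone offline.

## Localization precision

Per event with at least five localizations,
`σ_r = sqrt((s_x² + s_y²)/2)` with `s_x`, `s_y` the sample standard
deviations (n−1 denominator; the choice is ours) of the event's
coordinates; the dataset precision is the median over eligible events.
The combined precision is

```
σ_rc = <σ_r> · Σ_n w_n n^(−1/2) / Σ_n w_n
```

with `<σ_r>` the mean per-event precision and `w_n` the number of
eligible events with exactly `n` localizations. The nesting of the
defining expression `⟨⟨σ_r⟩/√n⟩_n` is genuinely ambiguous; we read it as
the *pooled* mean divided by √n and averaged over the n-histogram
("weighted by the occurrence of n"), and provide the per-event
alternative `mean(σ_i/√n_i)` behind `combined_sigma(method =
"per_event")` for sensitivity checks. The two coincide when precision
and event length are uncorrelated. The n ≥ 5 eligibility threshold is
applied to the combined statistics as well, since they reuse `<σ_r>`.
In 3D, `σ_z` is the plain sample SD of z; `σ_zc` follows the same
weighting. Precision is always computed on *unscaled* z; the 0.7 axial
display scaling (below) is applied at render time only.

## Drift correction

Sample drift is estimated from event mean positions (one point per
trace, at the event start time — events are seconds long, drift
timescales are minutes):

1. overlapping windows of ~2000 events (50% overlap; both configurable);
2. per window, a Gaussian rendering (σ = 2 nm; pixel 1 nm in 2D, 2 nm
   voxels in 3D to bound memory) over common bounds;
3. for *every* window pair, the cross-correlation on a 2× zero-padded
   grid; the peak is refined per axis by a log-quadratic (Gaussian) fit
   over a ±3-pixel neighborhood — small neighborhoods resist secondary
   peaks from structural periodicity;
4. a peak-significance score `(peak − median)/SD` of the correlation
   field gates each pair (default threshold 8: the extreme value of a
   featureless Gaussian correlation field of this size is ≈ 5, while
   genuinely matched windows score far higher);
5. per-window offsets solve the over-determined system
   `p_j − p_i = d_ij` in least squares (unweighted, all accepted pairs)
   with the gauge `mean(p) = 0`;
6. a natural cubic spline through (window-center time, offset) is
   evaluated at each event's start time and subtracted; outside the knot
   span the trace is clamped, not extrapolated.

The absolute offset is unobservable (gauge freedom), so recovered and
true drift curves are compared after removing their means. Redundant
cross-correlation needs *aperiodic* structure: on a perfect lattice the
correlation has equivalent peaks at lattice offsets, and drifts beyond
half a lattice constant alias. The test fixtures therefore use random
site structures.

## FRC resolution

The combined (per-event mean) x/y positions are split at random into two
halves; each half is binned into a plain count histogram (pixel 2 nm by
default, 1 nm in the tests' fixtures; padded to a power-of-two square),
and the ring-averaged correlation of the two Fourier transforms is
computed at one-bin ring width. Histograms rather than Gaussian
renderings: a Gaussian kernel multiplies both spectra by a known transfer
function and biases the crossing. No curve smoothing is applied; the
resolution is the inverse of the first frequency where the curve is below
1/7 *and stays below for one further ring* (a cheap guard against
single-ring noise dips), located by linear interpolation between the
bracketing rings. The random split is repeated (default 10 times, seeded)
and the resolutions averaged. Splits that never cross 1/7 mean the
resolution is beyond the Nyquist limit of the chosen pixel; they are
excluded with a warning rather than mapped to a number. Combined rather
than single localizations are essential: repeated localizations within
one binding event are not independent, and single-localization FRC
collapses to the localization precision.

## The CFR simulator

The center-frequency ratio compares the emission frequency with the
donut zero on the molecule against the mean over the outer TCP
exposures. For a perfect zero the center detects no signal, so the
measured center frequency is pure background from diffusing imager —
which is why the CFR grows with imager concentration and pinhole size
even for a perfectly centered molecule.

* **Excitation**: vectorial Richards–Wolf focal field of a circularly
  polarized vortex of charge 1 with handedness matched to the
  polarization — the configuration with an *exact* on-axis null (every
  azimuthal field order is nonzero, so every Bessel term vanishes at
  r = 0). The focal intensity is azimuthally symmetric in closed form,
  so fields are computed on an (r, z) table by Gauss–Legendre quadrature
  (96 nodes) of the aperture integrals and expanded to the grid; shifted
  donuts are evaluated from the same table, avoiding resampling error.
  The cited chirp-z acceleration of focus-field computation is an
  optimization, not different physics; direct quadrature is exact enough
  here and checked against an independent scalar vortex model in the
  tests.
* **Detection**: the emission-wavelength (680 nm) focal intensity,
  polarization-averaged, convolved per z-slice with a hard disc — the
  back-projected pinhole, 1 AU = 1.22·λ_det/NA. Larger pinholes admit
  more background volume; the simulator reproduces that monotonicity.
* **Effective PSF and CFR**: `h_eff,i = h_exc(· − r_i) · h_det` for each
  exposure i of the TCP (center + 6 outer points on the circle of
  diameter L; the exposure count is not standardized, so it is a
  parameter). Background `B_i = c ∫ h_eff,i dV` with
  1 nM = 6.022×10⁻¹⁰ molecules/nm³; signal `I_i = h_eff,i(0,0,0)`. Both
  are emission rates per unit single-molecule brightness, hence
  commensurate. Outer means are dwell-weighted (equal shares by
  default), and `CFR = (B_center + I_center)/(B̄_outer + Ī_outer)`.
* **Defaults that are ours**: NA = 1.4 oil (n = 1.518) — "realistic
  objective" values, not published ones; the center/outer dwell split;
  the integration cube of side 6·λ_det/NA (convergence documented by the
  grid-refinement test: halving the 40 nm test spacing moves the CFR by
  < 5%); an optional additive null floor `ε·peak` models imperfect
  zeros.

Photon shot noise and aberrations are out of scope; simulated CFR values
are noise-free expectations.

## Rendering

2D images are integer count histograms (default bin 4 nm; 1 nm for
close-ups) with half-open bins anchored at the bounding-box minimum
rounded down to a bin multiple — this makes rendering deterministic and
a coarse image an exact block-sum of a fine one over the same bounds.
3D renderings scale z by 0.7 (refractive-index mismatch convention of
the acquisition) and place Gaussian peaks of σ = 5 nm. TIFF output is
32-bit float, scaled to a recorded maximum for reader compatibility.

## The synthetic generator: what it does and does not show

The generator emulates the *export layer*: per docking site, binding
events arrive as a Poisson process at rate `k_on · c_imager` with
exponential bound times (a bound site cannot rebind, so per-site events
never overlap); bursts of valid last-iteration localizations on a fixed
1/`loc_rate` duty cycle (the instrument repeats the final iterations on
a fixed cycle, so regular — not Poisson — emission is the faithful
choice); isotropic Gaussian localization noise `sigma_true`; one valid
row per earlier iteration with proportionally coarser noise; terminal
non-valid rows; an `fbg` column jittered around its true value; and CFR
values drawn from a lognormal around a configurable median — a sampling
convenience so that median-CFR code paths are exercised; *physical* CFR
values come from the optics module. Drift models: none, linear, or a
natural-spline random walk, always starting at zero offset.

Published binding-rate constants for these imagers are not available, so
the defaults (`k_on = 1e-3 /s/nM` ≈ 1e6 /M/s, 2 nM, mean bound time
0.4 s, 50 localizations/s, σ = 2 nm, 20 kHz background) are arbitrary but
realistic test settings, chosen once and documented here; they are not
measurements. Not emulated at all: photon statistics, blinking and
bleaching, diffusion-limited imager transport, the on-line position
estimator, and on-line CFR filtering. Passing parameter-recovery tests
therefore demonstrates the correctness of the *estimators* on data
matching the export model — not the fidelity of that model to any
particular instrument.

## Problem sizes and numerical tolerances used in the tests

Fixtures are sized for tight statistical checks at interactive runtimes:
event statistics on ~200–350 events (60 random sites, 2000–3000 s);
precision recovery at σ ∈ {2, 3, 5} nm on ≥ 200 events with ≥ 10
localizations (10% tolerance — the χ-distribution spread of a median of
sample SDs); drift recovery on ~1750 events in 14 windows of 250 events
(2 nm RMS acceptance, 2 nm rendering pixels); FRC on up to ~1800
combined positions with σ_true = 5 nm so the resolution sits measurably
above the 1 nm-pixel Nyquist limit; optics on a 40 nm grid with a 20 nm
refinement check. Monte-Carlo assertions use 3-standard-error bounds
under fixed seeds.

## Known limitations

* Event extraction assumes trace IDs are not recycled within an
  acquisition; recycled IDs would merge distinct events.
* Drift estimation requires aperiodic structure and enough events per
  window; it refuses single-window datasets rather than guessing.
* The FRC pixel bounds the measurable resolution from below; the
  instrument software's exact pixel and repeat choices are unknown, so
  absolute FRC values should be compared across settings, not across
  tools.
* The CFR simulator models a molecule exactly at the pattern center;
  off-center molecules and shot noise — both present in measured CFR
  distributions — are out of scope.
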