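---
title: "Simulating proton minibeam FLASH delivery: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating proton minibeam FLASH delivery: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmbflash)
```

## The problem

Proton minibeam radiation therapy (pMBRT) spatially fractionates the dose
with a brass multi-slit collimator (MSC): parallel 1.0 mm slits at 2.8 mm
pitch produce alternating peak/valley stripes whose quality is summarized
by the peak-to-valley dose ratio (PVDR). Because the collimator blocks
most of the beam, conventional pencil-beam-scanned (PBS) delivery of a
minibeam field is slow; driving the same field at ultra-high dose rate
(UHDR / FLASH, beam current raised from ~1-2 nA to 125 nA) compresses the
delivery from minutes to seconds while the spatial pattern is set by the
collimator geometry alone.

`pmbflash` models this delivery chain end to end at desk scale: an
analytic proton pencil-beam model in water, Monte Carlo transport of spot
phase space through the MSC, hybrid dose scoring on a fine-in-y phantom
grid, pulsed delivery schedules, field-average and PBS (Folkerts)
dose-rate metrics, and PVDR / 1-D gamma profile analysis. Four bundled
presets (`flash-10`, `flash-6.5`, `conv-10`, `conv-6.5`) pin the study
conditions: 228 MeV / spot sigma 5.6 mm / 125 nA for UHDR versus
226 MeV / 3.4 mm / 1.88 nA for conventional optics, SADs 298 cm (x) and
970 cm (y), a 3 x 3 cm^2 raster of 49 spots at 5 mm spacing with 50 MU
per spot, and a 1 kHz / ~10 us synchrocyclotron pulse structure.

## Beam model

* **Range-energy**: the clinical power law `R = alpha E^p` with
  `alpha = 0.0022` cm/MeV^p and `p = 1.77` (water), accurate to ~1% at
  therapeutic energies; other materials scale the water range by a
  `range_scale` factor. Brass uses density 8.49 g/cm^3, radiation length
  1.55 cm and `range_scale = 0.105` (Cu70/Zn30-like), which makes both
  the 6.5 cm and the 10 cm septa opaque to primaries.
* **Depth dose**: a Bortfeld-style analytic Bragg curve — the power-law
  stopping term `(R - z)^(1/p - 1)` convolved with a Gaussian
  range-straggling kernel, sigma = 1.2% of the range. The singular
  endpoint is removed by a power substitution so the quadrature is
  smooth; the curve peaks within 2% of the range and is ~0 beyond
  1.05 R.
* **Divergence**: a virtual point source per scanning axis at the
  measured SAD. Spot sigma and spot-center positions scale with
  `(SAD - d)/SAD` upstream of isocenter. One source of the study quotes
  the y-axis SAD as 910 cm and another as 970 cm; the presets use 970 cm
  and the value is config-overridable.
* **Scattering**: Highland's formula, accumulated per transport step via
  the cumulative form `f(L) = L [1 + log10(L/X0)/9]^2` so the whole-path
  angle is recovered exactly for constant momentum; in water,
  Fermi-Eyges moments `sigma^2(z) = int (z-u)^2 T(u) du` with the
  scattering power T evaluated at the local residual energy.
* **Nuclear interactions**: primary-fluence attenuation
  `exp(-weq/lambda)` with `lambda = 110` cm water-equivalent, and no
  secondary transport. This is the single most consequential
  simplification (see *Limitations*).

## Collimator transport

Each spot is sampled at the collimator entrance plane (Gaussian per-axis
positions, directions through the per-axis virtual source) and stepped
through the MSC in 1 mm z-steps: straight-line advance in the air slits;
in brass, Gaussian angular kicks from the Highland accumulation plus
residual-range bookkeeping at `1/range_scale` water-cm per brass-cm,
with termination when the residual range is exhausted. Particles cross
slit/septum boundaries between steps, which is exactly how edge
scattering — the model's only source of valley dose — arises. A
perfect-absorber mode (no scattering, any septum contact kills) provides
the ray-trace limit: transmission of a broad parallel beam equals
`slit_width / pitch = 1/2.8`.

RNG streams are derived per (spot, stage) from the spot's grid position,
never from its delivery order, so per-spot results are identical between
scan patterns; the accumulated total is additionally summed in a
canonical coordinate order, making it bit-for-bit invariant under any
permutation of the delivery sequence.

The collimator exit face sits 5 cm upstream of the phantom surface by
default (the snout-to-phantom gap is not published; it is a
`collimator_spec` field). The phantom surface is placed at the isocenter
plane.

## Dose scoring

Full in-phantom Monte Carlo is unnecessary for the collimator-driven
lateral structure, so scoring is hybrid: surviving particles are grouped
into residual-range bins; at each grid depth plane their ray positions
are histogrammed (1 mm in x, 0.1 mm in y), weighted by the Bragg-curve
value and nuclear attenuation for the bin, and blurred with the
Fermi-Eyges sigma at that depth and bin energy. Voxel values are
point estimates at voxel centers — the 0.1 mm y-grid already
oversamples the 1 mm slits. The default analysis grid keeps a 51 x 501
transverse plane at the depths under study (2/4/6 cm, plus 8 and 12 cm
for depth-trend checks) rather than the full 400-plane phantom; any
`dose_grid` can be passed instead when a dense depth axis is needed
(e.g. for PDDs).

Absolute Gy-per-MU calibration is not published, so absolute dose enters
through a documented convention (`calibrate_dose`): the presets scale the
total map so the peak dose at 2 cm equals the printed peak average dose
rate times the delivery time (e.g. 8.4 Gy/s x 2.5 s = 21 Gy for
`flash-10`). PVDR and all ordering properties are independent of this
scale; only the PBS-threshold masking depends on it.

## Delivery and dose-rate metrics

A spot delivers `mu x charge_per_mu` nC at the mode's current, so its
duration is charge/current and the total time scales exactly as
1/current. `charge_per_mu = 0.1276` nC/MU is calibrated so that the
2450 MU field takes 2.5 s at 125 nA; the same value reproduces 166 s at
1.88 nA (the conventional current is quoted as a range; 1.88 nA is the
consistency choice that matches the printed time). Spot durations are
continuous; the 1 kHz pulse quantization is available as a per-pulse
expansion whose last partial pulse conserves charge exactly. Dead time
between spots defaults to 0 s (spot-switching times are not published)
and is configurable.

Two rate metrics are computed per voxel:

* **average rate** `D(x)/t_total`;
* **PBS (Folkerts) rate** `(D - 2 Dth)/(t1 - t0)`, with `t0`/`t1` the
  times at which the voxel's piecewise-linear cumulative curve reaches
  `Dth` and `D - Dth` (threshold 0.5 Gy by default). Voxels with
  `D <= 2 Dth` are masked invalid rather than zeroed, and a zero-length
  window returns an explicit infinite-rate sentinel. Crossing times use
  linear interpolation inside accrual segments, consistent with constant
  beam current during a spot; a dense-resampling brute-force oracle
  (`pbs_dose_rate_oracle`) provides an independent check.

The tabular summary reports PDR/VDR (average-rate field sampled at
peak/valley positions), PDR_PBS/VDR_PBS, and MDR_PBS as the maximum of
the valid PBS field at the depth. The study's "maximum instantaneous
dose" footnote is ambiguous between spot-level and pulse-level timing;
both fidelities are available (`pbs_config(fidelity =
"pulse-resolved")`) and are labelled, with neither asserted as *the*
published reading.

Note that the PBS rate does not dominate the average rate universally:
for a voxel whose accumulation window spans essentially the whole
delivery (bursts at both ends), `(D - 2 Dth)/(t1 - t0)` can fall below
`D/t_total`. Dominance holds for the high-dose voxels whose window is
much shorter than the field delivery, and that is what the tests assert.

## Profile analysis

PVDR uses a declared estimator (the published one is not specified): the
central 3 peaks and their adjacent valleys, each averaged over a
+/- 0.2 mm window, with uncertainty propagated from the per-window
standard deviations. Peak/valley positions are dose-weighted centroids
of the upper/lower 20% band inside half-pitch search windows around the
projected slit centers — robust against flat tops and Monte Carlo noise.
Profiles are averaged over a central 20 mm x-window. The 1-D gamma uses
3% (global) / 0.3 mm defaults — criteria are not published, and
sub-millimeter structure demands sub-pitch DTA — evaluated on the
central 95% of the overlap, with the evaluated curve treated piecewise
linearly and minimized exactly per segment.

## Synthetic film and scenarios

Film scans are emulated in dose units (the optical-density calibration
chain is out of scope): dose resampled to a 0.085 mm pixel grid
(300 dpi) with multiplicative Gaussian noise, default CV 2% — the study
publishes no noise statistics, so the default is exposed. A lognormal
daily output factor (CV 5%) emulates the day-to-day UHDR output
fluctuation; the film normalization step (`scale_profile` least-squares
factor) recovers it exactly in the noiseless limit and unbiasedly under
multiplicative noise. What the generator does *not* emulate: film LET
quenching, scanner lateral response, OD-to-dose calibration error. A
gamma pass against synthetic film therefore validates pipeline
consistency, not film physics.

## Problem sizes and numerical choices

Full-scale runs use 1e5 histories per spot (4.9e6 protons per preset),
1 mm transport steps, 2 cm residual-range bins for scoring, and
FFT-based separable Gaussian blurs (kernels below 0.25 bins are treated
as deltas; negative FFT ringing is clipped at zero). Unit tests run
reduced fixtures (8e3 histories) and the PVDR statistics quoted below
come from the full-scale runs with seed 1. A preset simulates in roughly
one to two minutes on one CPU.

## What the model reproduces — and what it cannot

With the stated physics, the pipeline reproduces the *structural*
results: the 10 cm collimator gives a higher PVDR than the 6.5 cm one at
2 cm; the modulation decays from 2 cm to 6 cm and vanishes by ~12 cm
(PVDR < 1.3); total dose is exactly scan-order invariant while the PBS
rate field is strongly pattern-dependent; delivery is ~66x faster at
125 nA; and the PBS rate is insensitive to the threshold choice
(< 20% over 0.1-1.0 Gy).

It does **not** reproduce the published PVDR magnitudes: simulated
values at 2 cm are ~3-5x the measured/TOPAS ones (e.g. ~21 vs 4.36 for
the 10 cm MSC under UHDR optics, ~7.8 vs 2.57 for the 6.5 cm one, at
1e5 histories/spot with seed 1). The reason is structural. In this
model the only valley dose at shallow depth is collimator-edge-scattered
primaries; measured valleys are dominated by nuclear secondaries and
non-Gaussian scatter tails, which are deliberately outside the model
(no secondary transport, Gaussian-core MCS only). A related signature:
for the 6.5 cm collimator the model's PVDR peaks at 4 cm rather than
decreasing from 2 cm, because edge-scattered primaries with short
residual ranges Bragg-peak near 2 cm and inflate that valley, while the
Fermi-Eyges blur at 4 cm (sigma ~0.23 mm) is still too small to
compensate. The threshold-sensitivity of the peak PBS rate is also
larger here (~34% over 0.1-1.0 Gy) than the published qualitative
"little impact": with spot-uniform accrual and 5.6 mm spots on a 5 mm
raster, a low threshold stretches the accumulation window out to the
faint first- and last-row contributions. Users comparing against film
data should treat simulated PVDRs as upper bounds with correct
ordering, not as absolute predictions.

## Reproducing the study-shaped outputs

```r
cfg <- make_scenario("flash-10")
sim <- run_simulate(cfg)                      # 49 spots, seeded
dr  <- run_doserate(sim, cfg)                 # per-depth summary table
an  <- run_analyze(sim$total, cfg)            # PVDR at 2/4/6 cm
```

`scripts/acceptance.R` re-runs the four presets from scratch and writes
the 2 cm PVDRs as JSON; see the README for invocation.
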