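---
title: "Phasor and reconvolution-fit methods in fliphasor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor and reconvolution-fit methods in fliphasor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fliphasor)
```

This vignette is the package's account of the science it implements: the
models, the parameters that matter, the numerical conventions, and what
the synthetic-data tests do and do not demonstrate about real data.

## The data model

A fluorescence lifetime imaging (FLIM) acquisition is a photon-count cube
`counts[time_bin, row, col]`: for each pixel, a histogram of photon
arrival times within the laser period `T` (ns). The package represents
time by bin centers `t_k ∈ [0, T)` on the `fli_time_axis`; the repetition
frequency is `f = 1/T` (reported in MHz) and the angular frequency at
harmonic `n` is `ω = 2πn/T` (1/ns). Storing centers rather than edges
removes the half-bin ambiguity from every downstream formula. Counts are
non-negative; they may become real-valued after pile-up correction.

Assumptions baked into the analysis: photon counting is Poisson;
the decay is a sum of one or two exponentials; the excitation is
periodic, so every observed decay is the steady-state wrap of the
impulse response over the period; the IRF is measured on the same time
grid as the data.

## Phasors, calibration, and the universal circle

The phasor of a decay with counts `c_k` is

    g = Σ c_k cos(ω t_k) / Σ c_k,    s = Σ c_k sin(ω t_k) / Σ c_k.

Raw phasors are rotated and demodulated by the instrument; calibration
divides by the phasor of a reference of known lifetime `τ_ref` (complex
division: moduli divide, phases subtract) and multiplies by the
universal-circle phasor of `τ_ref`. An IRF is the `τ_ref = 0` reference.
Calibration can be a single phasor or per-pixel (a phasor image), the
latter being the relevant mode for SPAD cameras whose gate position
varies across the array. All phasor arithmetic is double precision.

Two useful scalar summaries are the phase and modulation lifetimes,
`τ_φ = (s/g)/ω` and `τ_m = sqrt(1/(g²+s²) − 1)/ω`; they agree on the
universal circle and split (`τ_m > τ_φ`) strictly inside it, a standard
heterogeneity indicator.

### Reference finding by the principal axis of inertia

A two-component population places its (calibrated) phasors on a chord of
the universal circle. The reference-finding operation computes the mean
and 2×2 second-moment matrix of the phasor cloud — its axis of inertia —
takes the major (or, on request, minor) eigenvector, and intersects the
line through the mean along that axis with the circle of center (½, 0),
radius ½, by solving the quadratic. The two intersections are reported
as a `ReferencePair` with their universal-circle lifetimes, `p1` being
the larger-`g` (shorter-lifetime) intersection — a deterministic
ordering that fixes the meaning of `f1` downstream.

Design choices here were genuinely open:

* **Weights.** The inertia tensor is computed with equal weight per
  phasor by default; an intensity-weighting option exists. Equal weights
  make the result independent of ROI brightness, which is the right
  default when ROIs are comparable cells.
* **Degeneracies.** An isotropic cloud (eigenvalue ratio below
  `min_axis_ratio`) is an error — the axis is not defined. A tangent
  axis (discriminant ≈ 0, below 1e-24) returns a *degenerate* pair
  (`p1 == p2`) with a warning rather than an error, since the single
  tangency point is still informative. A line that misses the circle is
  an error.
* **Conditioning.** The axis is only as well determined as the cloud's
  elongation: the angular error scales like the perpendicular/parallel
  spread ratio divided by √N. A population with no lifetime
  heterogeneity gives an isotropic (noise-only) cloud and the algorithm
  rightly refuses it. This is why the synthetic scenes include
  population heterogeneity (below).

### Decomposition and the amplitude-averaged lifetime

A phasor `p` is decomposed by orthogonal projection onto the reference
segment: `f1 = ((p − p2)·(p1 − p2))/|p1 − p2|²`, clamped to [0, 1] (and
flagged) rather than extrapolated; the perpendicular distance is the
residual, and an optional residual bound marks outliers invalid so maps
and histograms can exclude them. A perpendicular band is used as the
confinement region because it is the natural shape for "close to the
mixture segment".

Phasor fractions are *intensity* fractions. Converting to
pre-exponential amplitude fractions (`a_i ∝ f_i/τ_i`) gives the
amplitude-averaged lifetime

    ⟨τ⟩ₐ = Σ a_i τ_i / Σ a_i = 1 / (f1/τ1 + f2/τ2),

which always lies in `[τ1, τ2]`.

## The reconvolution forward model and its discretization

The fitted model is the steady-state periodic decay

    F(t) = Σ_i a_i exp(−t/τ_i) / (1 − exp(−T/τ_i)),   t ∈ [0, T)

circularly convolved with the unit-normalized IRF, plus a constant
background `B` (counts/bin). The IRF time shift (the classic "color
shift" nuisance) is a free parameter by default, implemented by periodic
linear interpolation of the IRF.

One numerical convention deserves emphasis. All curves are sampled at
bin centers, but the difference grid of two center grids is the *edge*
grid: a naive FFT convolution of center-sampled sequences carries a
half-bin phase bias, so the phasor of modeled data would differ from
(IRF phasor) × (decay phasor) by `exp(−iωΔt/2)` — about 0.06 ns of
systematic lifetime error at 256 bins. The package therefore evaluates
the wrapped exponential on the lag grid `mΔt`, assigning the lag-0
sample the midpoint value of its jump discontinuity (the "half first
channel" convention of classic TCSPC fitting). With that convention the
discrete circular convolution reproduces the continuous reconvolution
integral to spectral accuracy: the calibrated phasor of a modeled
mono-exponential sits within 2.4e-7 of its universal-circle point at
4096 bins, and phasor-derived and fitted lifetimes agree to ~4e-4 ns at
256 bins.

### Estimators

Three objectives are offered over an optional fit window (the model is
always computed over the full period):

* unweighted SSE `Σ(n_k − m_k)²`;
* weighted χ² with Neyman weights `σ_k² = max(n_k, 1)` — the standard
  TCSPC choice, and the definition used for every reported reduced χ²
  (`dof = #bins − #free parameters`);
* Poisson deviance `2Σ[m_k − n_k + n_k ln(n_k/m_k)]` (zero-count bins
  contribute `m_k`), the maximum-likelihood objective. Among the several
  MLE variants in the literature, the deviance was chosen because it is
  the likelihood-ratio form whose minimum coincides with the Poisson
  MLE and whose value doubles as a goodness-of-fit statistic.

Least-squares fits use Levenberg–Marquardt with box bounds
(`τ ∈ [1e-3, 1e3]` ns, `a ≥ 0`, `B ≥ 0`, `|shift| ≤ T/2`); the MLE is a
bounded quasi-Newton (L-BFGS-B) refinement of the deviance started from
the weighted-NLSF optimum — on noiseless data the start is already the
optimum, and on noisy data the refinement converges in a handful of
iterations. Convergence tolerances: relative objective change below
1e-12 (LM `ftol`/`ptol`), 500 iterations maximum; non-convergence is a
flag on the result, not an exception.

Initialization is deterministic (no random restarts): `B` from the
minimum bin, `τ` from a log-linear regression on the decay tail, the
amplitude from total counts via `Σ e^{−t_k/τ} ≈ τ/Δt (1 − e^{−T/τ})`;
two-component starts split the single-τ estimate by ×2 and ÷2.
Two-component results are reported in canonical order `τ1 < τ2`, which
resolves the label-switching ambiguity. Pixel-wise fitting shares one
initialization derived from the global (summed) decay, scaled per pixel,
so results are independent of pixel visiting order.

## Preprocessing conventions

* **Binning** sums non-overlapping blocks (k×k spatial, k temporal);
  partial blocks are dropped, not padded, so every retained output
  element aggregates the same number of inputs; totals over the retained
  region are conserved exactly. Temporal binning averages the merged bin
  centers.
* **Background subtraction** (constant or estimated from a pre-pulse
  window) clamps at zero to preserve the non-negative count invariant;
  the clamp bias is negligible at count levels where analysis is
  meaningful. The per-pixel estimate is retrievable.
* **Pile-up correction** inverts the gated single-photon saturation map
  `n = N(1 − e^{−m/N})` with `N` exposures per bin:
  `m = −N ln(1 − n/N)`. This is the gated-camera regime; counts at or
  above `N` are a hard error naming the offending pixel and bin.
* **Thresholded ROIs** are connected components (8-connectivity by
  default, matching typical blob behavior in cell masks; 4 on request),
  with a single-ROI variant. Pixel coordinates are 0-based `(row, col)`,
  row 0 at top, the raster order of the mask TIFF.

## Maps, histograms, peak fitting

Parameter maps carry an explicit unset state (`NA`; empty fields in CSV
export, since NaN dialects vary across readers). Histograms run over set
values only and conserve their count under any binning. Multi-peak
Gaussian fits use the area parameterization
`count(x) = Σ_j area_j · N(x; mean_j, σ_j) · binwidth`, deterministic
initialization from the tallest local maxima, and box bounds: means
within the histogram range and `σ ≥ binwidth/2`, because a histogram
cannot resolve structure below its bin width — without that bound a
sparse histogram lets a near-delta Gaussian sit on a single tall bin.

When the workflow histograms per-ROI ⟨τ⟩ₐ values (a small sample — one
entry per cell), the histogram range is padded 75% beyond the data range
(`hist_pad`). A 20-sample histogram over its own range shows only the
flat top of the underlying distribution, leaving a Gaussian's width and
center ill-determined; the padded zero-count tail bins anchor the fit.

Calibrated-quantity maps (e.g. membrane potential from an experimental
V(τ) curve) use piecewise-linear interpolation, mark out-of-range values
unset, and can enforce curve monotonicity.

## The synthetic scene generator

`simulate_scene()` emulates the target experiment: non-overlapping
ellipsoidal "cells" (rejection placement, semi-axes 3–6 px) on a 96×96
grid, 256 time bins at 78.02 MHz, a Gaussian IRF of 0.4 ns FWHM centered
at 1 ns, one lifetime population with `τ = (1, 3.5)` ns mixed 60/40 by
amplitude, and 10⁵ expected photons per cell with per-bin Poisson noise.
Every output is a pure function of the seed and parameters.

Two generator choices matter and are deliberate:

* **Cell-to-cell heterogeneity.** The amplitude fraction gets a per-cell
  Gaussian jitter of sd 0.05 (⟨τ⟩ₐ CV ≈ 6%), the kind of spread a
  voltage-sensitive-dye population shows. Beyond realism, the
  principal-axis algorithm *needs* spread along the chord: with
  identical cells the phasor cloud is isotropic shot noise and the axis
  is undefined. Under these conditions the 20-ROI workflow recovers the
  reference lifetimes within ~2% and per-cell ⟨τ⟩ₐ within ~2%
  (checked across seeds).
* **Per-pixel IRF variation** is modeled as a smooth shift field — the
  minimal structure that makes per-pixel calibration and per-pixel
  reconvolution testable. Width variation, optical blur, crosstalk and
  afterpulsing are not modeled.

What passing tests therefore show: the algorithms are correct on data
that exactly follow the stated decay, IRF and noise models. What they do
not show: robustness to model violations in real data — scattered
excitation light, autofluorescence backgrounds with their own lifetimes,
detector afterpulsing, dead-time distortions beyond the single-photon
pile-up model, or segmentation errors upstream of the mask.

## File formats

The HDF5 dialect is one 3-D double dataset (default `/counts`, C-order
time × row × col) with `period_ns` and `bin_centers_ns` attributes and
`meta:*` string attributes; a layout config remaps the dataset path,
time-axis position and period so third-party cubes can be ingested
without hard-coding a guess about their internal layout. An explicit
layout override wins over a stored attribute. Label masks are
single-plane integer TIFFs (float storage accepted only if integral).
Calibrations, reference pairs and ROI sets persist as versioned JSON
sidecars (schema `fliphasor/<type>@1`); XML offers the same information
with a second schema, so JSON alone is supported. Text round trips are
lossless to ≥ 15 significant digits; with fixed seeds all CSV/JSON
outputs are byte-identical across runs.

## Problem sizes

The shipped tests run phasor identities at 256–4096 bins, fitting at
128–256 bins (100-replicate bias checks at 128 bins), pixel-wise fits on
up to 6×6 images, and end-to-end scenes of 20 cells on 96×96 grids —
sizes chosen so the whole suite completes in well under a minute while
every statistical check retains the power it needs. The acceptance
script re-runs the 20-cell workflow and the fitting checks from scratch
at the given seed.

## Known limitations

* Two components at most; no global (linked-lifetime) fitting across
  pixels, no stretched exponentials, no multi-harmonic joint unmixing.
* The pile-up model is the gated-camera (binomial saturation) regime;
  classic TCSPC dead-time pile-up is not implemented (the config leaves
  room for it).
* The IRF shift is interpolated linearly; sub-bin structure narrower
  than the grid is not representable.
* Photon-stream (macrotime/microtime) ingestion and vendor formats are
  out of scope; cubes arrive via HDF5 or the generator.
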