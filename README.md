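# fliphasor

Phasor and decay-fit analysis of fluorescence lifetime imaging (FLIM) data
in R.

Fluorescence lifetime imaging records, at every pixel of an image, the
temporal decay of fluorescence emission after pulsed excitation. The decay
carries information — probe environment, FRET state, membrane potential —
that intensity alone does not. `fliphasor` implements the two standard
routes for extracting it from a photon-count cube (time bin × row × column):

* **Phasor analysis.** Each decay is projected onto one point
  `(g, s)` at harmonic *n* of the laser repetition frequency
  (`ω = 2πn/T`, `T` the laser period):

  ```
  g = Σ c_k cos(ω t_k) / Σ c_k      s = Σ c_k sin(ω t_k) / Σ c_k
  ```

  After calibration with the instrument response function (IRF — the
  phasor associated with lifetime τ = 0), single-exponential decays fall
  on the *universal circle* (center (½, 0), radius ½), where
  `g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)`; two-component mixtures fall on
  the chord between their component phasors. The package implements the
  automatic reference-finding algorithm that intersects the **principal
  axis of inertia** of a phasor cloud with the universal circle, yielding
  two single-exponential references (τ₁, τ₂). Linear decomposition of any
  phasor onto the reference segment gives intensity fractions f₁, f₂ and
  the amplitude-averaged lifetime `⟨τ⟩ₐ = 1/(f₁/τ₁ + f₂/τ₂)`.
  Calibration may be a single phasor or **per-pixel** (as SPAD cameras
  with gate-position nonuniformity require).

* **Reconvolution decay fitting.** Single- or double-exponential models,
  circularly convolved with the measured IRF over the laser period
  (steady-state periodic excitation, free IRF shift), fitted by
  unweighted least squares, Neyman-weighted χ²
  (`σ_k² = max(n_k, 1)`), or Poisson maximum likelihood (deviance
  `2Σ[m_k − n_k + n_k ln(n_k/m_k)]`) — per decay, per ROI, or pixel-wise
  with per-pixel IRFs.

Around the core sit ROI tools (label-mask TIFFs from StarDist/Fiji-style
segmentation, intensity thresholds, grids, merge/explode), dataset
conditioning (spatial/temporal binning, background subtraction, pile-up
correction), parameter maps with multi-peak Gaussian histogram fitting and
calibration-curve mapping (e.g. lifetime → membrane potential), HDF5 /
TIFF / CSV / JSON I/O, a ground-truthed synthetic scene generator, and a
config-driven workflow driver. It is written for microscopists and
methods developers who want a scriptable, testable version of the
standard interactive FLIM analysis pipeline.

## Worked example

The synthetic generator emulates a voltage-sensitive-dye experiment: a
field of cell-shaped ROIs with bi-exponential decays (lifetimes 1 and
3.5 ns, 60/40 amplitude mix with cell-to-cell jitter) at a 78.02 MHz
repetition rate, Poisson counting noise, 10⁵ photons per cell.

```r
library(fliphasor)

scene <- simulate_scene(n_cells = 20, shape = c(96, 96),
                        counts_per_cell = 1e5, seed = 1)
rois <- rois_from_labels(scene$mask)
ds <- scene$dataset
ds
#> <fli_dataset> 96 x 96 pixels, 256 time bins, period 12.8172 ns, 1.999e+06 counts
rois
#> <fli_roi_set> 20 ROIs on a 96 x 96 grid (37-105 pixels)

# IRF calibration (tau_ref = 0) and calibrated per-ROI phasors
axis <- ds$time_axis
cal <- phasor_calibration(decay_phasor(scene$truth$irf, axis), 0)
roi_phasors <- lapply(rois$rois, function(r)
  calibrate(decay_phasor(roi_decay(ds, r), axis), cal))

# universal-circle references from the principal axis of the phasor cloud
refs <- principal_axis_uc_references(roi_phasors)
refs
#> <fli_reference_pair> tau1 = 1.005 ns, tau2 = 3.502 ns
#>   all phasors

# two-component decomposition -> amplitude-averaged lifetime per cell
tau_a <- vapply(roi_phasors, function(p)
  amplitude_avg_lifetime(decompose_phasor(p, refs), refs), numeric(1))
truth <- vapply(scene$truth$cells, `[[`, numeric(1), "tau_avg_ns")
head(cbind(estimated = tau_a, truth = truth), 4)
#>      estimated  truth
#> [1,]    1.9500 1.9636
#> [2,]    1.7453 1.7365
#> [3,]    1.9064 1.9075
#> [4,]    1.9810 1.9764
max(abs(tau_a - truth) / truth)     # max relative error: 1.0%
```

The recovered references sit within 0.5% of the generator's component
lifetimes, and every cell's ⟨τ⟩ₐ is recovered within 1% here. The same
decays can be fitted by iterative reconvolution instead:

```r
ft <- fit_decay(roi_decay(ds, rois$rois[[1]]), scene$truth$irf, axis,
                n_components = 2, method = "mle")
ft
#> <decay_fit> mle, 2 component(s)
#>   tau1 = 1.027 ns (a1 = 1623), tau2 = 3.572 ns (a2 = 932)
#>   B = 0, shift = 0.0002385 ns, chi2_red = 1.182
```

`fit_decay()` returns a classed model object with `coef()`, `summary()`,
`predict()`, `residuals()` and `simulate()` methods; `fit_image()` maps
it over all valid pixels. The whole pipeline is also available as one
call, `run_workflow(config)`, which writes every intermediate
(calibration, references, per-ROI table, lifetime map, histogram +
Gaussian peak fit, log) to an output directory; `inst/cli/fliphasor.R` is
a thin command-line wrapper over it.

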