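test_that("decay phasors honor the delta and uniform limits", {
  ax <- ax_default(256)
  # all counts at t = 0
  p <- decay_phasor(decay_curve(0, 100), ax)
  expect_equal(c(p$g, p$s), c(1, 0))

  # uniform counts over one full period (centers symmetric about T/2)
  u <- decay_curve(ax$bin_centers_ns, rep(7, 256))
  pu <- decay_phasor(u, ax)
  expect_lt(abs(pu$g), 1e-12)
  expect_lt(abs(pu$s), 1e-12)

  expect_error(decay_phasor(decay_curve(ax$bin_centers_ns, rep(0, 256)), ax),
               "empty")
})

test_that("a discretized exponential calibrated by a delta IRF hits (0.5, 0.5)", {
  ax <- time_axis(4096, frequency_MHz = 78.02)
  tau <- 1 / angular_frequency(ax)
  d <- simulate_decay(1, tau, irf = delta_irf(ax), axis = ax,
                      total_counts = 1e6, noiseless = TRUE)
  cal <- phasor_calibration(decay_phasor(delta_irf(ax), ax), 0)
  pc <- calibrate(decay_phasor(d, ax), cal)
  expect_lt(abs(pc$g - 0.5), 1e-4)
  expect_lt(abs(pc$s - 0.5), 1e-4)
})

test_that("phasor images agree with a per-pixel loop oracle", {
  cube <- random_cube(32, 4, 5, lambda = 20, seed = 12)
  ds <- fli_dataset(cube, ax_default(32))
  pim <- phasor_image(ds)
  for (r in 1:4) for (cc in 1:5) {
    p <- decay_phasor(decay_curve(ds$time_axis$bin_centers_ns,
                                  cube[, r, cc]), ds$time_axis)
    expect_equal(pim$g[r, cc], p$g)
    expect_equal(pim$s[r, cc], p$s)
  }

  # homogeneous cube -> constant maps
  h <- fli_dataset(array(rep(cube[, 1, 1], 6), c(32, 2, 3)), ax_default(32))
  ph <- phasor_image(h)
  expect_equal(max(ph$g) - min(ph$g), 0)
  expect_equal(max(ph$s) - min(ph$s), 0)

  # single pixel
  one <- fli_dataset(array(cube[, 2, 2], c(32, 1, 1)), ax_default(32))
  p1 <- phasor_image(one)
  expect_equal(p1$g[1, 1],
               decay_phasor(decay_curve(one$time_axis$bin_centers_ns,
                                        cube[, 2, 2]), one$time_axis)$g)
})

test_that("calibration is complex division times the reference UC phasor", {
  ax <- ax_default()
  raw <- phasor(0.3, 0.4, 1, ax$frequency_MHz)
  ident <- phasor_calibration(phasor(1, 0, 1, ax$frequency_MHz), 0)
  pc <- calibrate(raw, ident)
  expect_equal(c(pc$g, pc$s), c(0.3, 0.4))

  self <- phasor_calibration(raw, 0)
  ps <- calibrate(raw, self)
  expect_equal(c(ps$g, ps$s), c(1, 0))

  expect_error(calibrate(raw, phasor_calibration(
    phasor(0, 0, 1, ax$frequency_MHz), 0)), "degenerate")
})

test_that("an IRF-convolved decay calibrates onto the universal circle", {
  ax <- time_axis(4096, frequency_MHz = 78.02)
  irf <- gauss_irf(ax)
  d <- simulate_decay(1, 2.5, irf = irf, axis = ax, total_counts = 1e6,
                      noiseless = TRUE)
  cal <- phasor_calibration(decay_phasor(irf, ax), 0)
  pc <- calibrate(decay_phasor(d, ax), cal)
  expect_lt(phasor_dist(pc, uc_phasor(2.5, axis = ax)), 1e-3)
})

test_that("per-pixel calibration corrects a spatially varying IRF shift", {
  ax <- ax_default(256)
  shift_field <- function(r, cc) 0.01 * (r + cc)   # up to ~0.6 ns
  sc <- simulate_scene(n_cells = 3, shape = c(32, 32), seed = 6,
                       counts_per_cell = 1e6,
                       lifetime_populations = list(
                         list(tau1_ns = 1.0, tau2_ns = 3.5,
                              a1_fraction = 0.6, a1_jitter = 0, weight = 1)),
                       per_pixel_shift = shift_field, axis = ax,
                       irf = gauss_irf(ax))
  ds <- sc$dataset
  # build the per-pixel IRF phasor image from the known shift field
  base <- gauss_irf(ax)
  gm <- matrix(NA_real_, 32, 32); sm <- gm
  for (r in 1:32) for (cc in 1:32) {
    sh <- shift_field(r - 1, cc - 1)
    irf_rc <- decay_curve(ax$bin_centers_ns,
                          model_decay(decay_params(1, 1e-3, shift_ns = sh),
                                      base, ax))
    p <- decay_phasor(irf_rc, ax)
    gm[r, cc] <- p$g; sm[r, cc] <- p$s
  }
  vm <- validity_mask(ds, 50)
  pim <- phasor_image(ds, mask = vm)
  cal <- phasor_calibration(phasor_image_new(gm, sm, vm, 1, ax$frequency_MHz),
                            reference_lifetime_ns = 1e-3)
  pc <- calibrate(pim, cal)
  # uncalibrated phase lifetimes drift with the shift gradient ...
  w <- angular_frequency(ax)
  cells <- unclass(vm) & unclass(sc$mask) > 0
  tau_raw <- ((pim$s / pim$g) / w)[cells]
  # ... but per-pixel calibration collapses them to the population value
  tau_cal <- ((pc$s / pc$g) / w)[cells]
  expect_gt(stats::sd(tau_raw, na.rm = TRUE),
            2 * stats::sd(tau_cal, na.rm = TRUE))
  expect_lt(stats::sd(tau_cal, na.rm = TRUE), 0.06)
})

test_that("universal-circle map and its inverse agree to 1e-12", {
  ax <- ax_default()
  w <- angular_frequency(ax)
  expect_equal(c(uc_phasor(0, w)$g, uc_phasor(0, w)$s), c(1, 0))

  p <- uc_phasor(1 / w, w)
  expect_equal(c(p$g, p$s), c(0.5, 0.5), tolerance = 1e-14)

  expect_equal(uc_lifetime(uc_phasor(3.7, axis = ax), w), 3.7,
               tolerance = 1e-12)

  for (tau in c(0.01, 0.1, 0.5, 1, 2, 3.7, 10, 50, 100))
    expect_equal(uc_lifetime(uc_phasor(tau, w), w), tau,
                 tolerance = 1e-12 * max(tau, 1))

  off <- phasor(0.3, 0.1, 1, ax$frequency_MHz)
  expect_error(uc_lifetime(off, w), "circle")
})

test_that("phase and modulation lifetimes behave on and off the circle", {
  ax <- ax_default()
  w <- angular_frequency(ax)
  on <- phase_mod_lifetimes(phasor(0.5, 0.5, 1, ax$frequency_MHz), w)
  expect_equal(on$tau_phase_ns, 1 / w, tolerance = 1e-12)
  expect_equal(on$tau_mod_ns, 1 / w, tolerance = 1e-12)

  zero <- phase_mod_lifetimes(phasor(1, 0, 1, ax$frequency_MHz), w)
  expect_equal(zero$tau_phase_ns, 0)
  expect_equal(zero$tau_mod_ns, 0)

  inner <- phase_mod_lifetimes(phasor(0.55, 0.35, 1, ax$frequency_MHz), w)
  expect_equal(inner$tau_phase_ns, (0.35 / 0.55) / w, tolerance = 1e-12)
  expect_equal(inner$tau_mod_ns, sqrt(1 / 0.4250 - 1) / w, tolerance = 1e-12)
  expect_gt(inner$tau_mod_ns, inner$tau_phase_ns)

  expect_warning(out <- phase_mod_lifetimes(
    phasor(1.1, 0.2, 1, ax$frequency_MHz), w), "modulus")
  expect_true(is.na(out$tau_mod_ns))
  expect_error(phase_mod_lifetimes(phasor(-0.1, 0.2, 1, ax$frequency_MHz), w),
               "undefined")
})

test_that("phasors are linear in summed decays (count-weighted mean)", {
  ax <- ax_default(128)
  set.seed(31)
  for (i in 1:5) {
    a <- decay_curve(ax$bin_centers_ns, rpois(128, 30))
    b <- decay_curve(ax$bin_centers_ns, rpois(128, 8))
    pa <- decay_phasor(a, ax); pb <- decay_phasor(b, ax)
    ps <- decay_phasor(decay_curve(ax$bin_centers_ns, a$counts + b$counts),
                       ax)
    na <- sum(a$counts); nb <- sum(b$counts)
    expect_equal(ps$g, (na * pa$g + nb * pb$g) / (na + nb), tolerance = 1e-12)
    expect_equal(ps$s, (na * pa$s + nb * pb$s) / (na + nb), tolerance = 1e-12)
  }
})

test_that("noiseless two-component mixtures land on the reference chord", {
  ax <- time_axis(4096, frequency_MHz = 78.02)
  irf <- gauss_irf(ax)
  cal <- phasor_calibration(decay_phasor(irf, ax), 0)
  p1 <- uc_phasor(0.8, axis = ax)
  p2 <- uc_phasor(3.5, axis = ax)
  chord <- c(p2$g - p1$g, p2$s - p1$s)
  for (f1 in c(0, 0.25, 0.5, 0.8, 1)) {
    # intensity fraction f1 of tau1: amplitudes a_i = f_i / tau_i
    amps <- c(f1 / 0.8, (1 - f1) / 3.5)
    amps <- amps[amps > 0]
    taus <- c(0.8, 3.5)[c(f1 > 0, f1 < 1)]
    d <- simulate_decay(amps, taus, irf = irf, axis = ax,
                        total_counts = 1e6, noiseless = TRUE)
    pc <- calibrate(decay_phasor(d, ax), cal)
    # perpendicular distance to the chord
    v <- c(pc$g - p1$g, pc$s - p1$s)
    dist <- abs(v[1] * chord[2] - v[2] * chord[1]) / sqrt(sum(chord^2))
    expect_lt(dist, 1e-6)
  }
})

test_that("calibrating a decay by itself with its own lifetime is exact", {
  ax <- ax_default(512)
  irf <- gauss_irf(ax)
  d <- simulate_decay(1, 3.1, irf = irf, axis = ax, total_counts = 1e6,
                      noiseless = TRUE)
  p <- decay_phasor(d, ax)
  cal <- phasor_calibration(p, reference_lifetime_ns = 3.1)
  pc <- calibrate(p, cal)
  expect_equal(c(pc$g, pc$s),
               c(uc_phasor(3.1, axis = ax)$g, uc_phasor(3.1, axis = ax)$s),
               tolerance = 1e-14)
})
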