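test_that("two point-clusters on the circle are recovered exactly", {
  ax <- ax_default()
  pa <- uc_phasor(1, axis = ax)
  pb <- uc_phasor(4, axis = ax)
  cloud <- c(replicate(10, phasor(pa$g, pa$s, 1, ax$frequency_MHz),
                       simplify = FALSE),
             replicate(10, phasor(pb$g, pb$s, 1, ax$frequency_MHz),
                       simplify = FALSE))
  refs <- principal_axis_uc_references(cloud)
  expect_equal(refs$tau1_ns, 1, tolerance = 1e-6)
  expect_equal(refs$tau2_ns, 4, tolerance = 1e-6)
  expect_gt(refs$p1$g, refs$p2$g)   # p1 = shorter lifetime = larger g
})

test_that("a tangent principal axis yields a flagged degenerate pair", {
  f <- 78.02
  pts <- list(phasor(0.30, 0.5, 1, f), phasor(0.42, 0.5, 1, f),
              phasor(0.58, 0.5, 1, f), phasor(0.70, 0.5, 1, f))
  expect_warning(refs <- principal_axis_uc_references(pts), "tangent")
  expect_true(refs$degenerate)
  expect_equal(refs$tau1_ns, refs$tau2_ns)
  expect_equal(c(refs$p1$g, refs$p1$s), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("a line missing the circle and an isotropic cloud are errors", {
  f <- 78.02
  high <- list(phasor(0.1, 0.9, 1, f), phasor(0.9, 0.9, 1, f),
               phasor(0.5, 0.9, 1, f))
  expect_error(principal_axis_uc_references(high), "intersect")

  set.seed(41)
  th <- runif(200, 0, 2 * pi)
  iso <- lapply(seq_along(th), function(i)
    phasor(0.5 + 0.1 * cos(th[i]), 0.3 + 0.1 * sin(th[i]), 1, f))
  expect_error(principal_axis_uc_references(iso, min_axis_ratio = 1.5),
               "isotropic")
})

test_that("jittered chord clouds recover the endpoint lifetimes within 5%", {
  ax <- ax_default()
  set.seed(17)
  pa <- uc_phasor(0.8, axis = ax)
  pb <- uc_phasor(3.5, axis = ax)
  f1 <- runif(500)
  jit <- 0.004
  g <- f1 * pa$g + (1 - f1) * pb$g + rnorm(500, 0, jit)
  s <- f1 * pa$s + (1 - f1) * pb$s + rnorm(500, 0, jit)
  cloud <- lapply(seq_len(500), function(i)
    phasor(g[i], s[i], 1, ax$frequency_MHz))
  refs <- principal_axis_uc_references(cloud)
  expect_lt(abs(refs$tau1_ns - 0.8) / 0.8, 0.05)
  expect_lt(abs(refs$tau2_ns - 3.5) / 3.5, 0.05)
})

test_that("phasor-plot selections restrict the reference fit", {
  ax <- ax_default()
  set.seed(23)
  pa <- uc_phasor(1, axis = ax)
  pb <- uc_phasor(3, axis = ax)
  f1 <- runif(300)
  good_g <- f1 * pa$g + (1 - f1) * pb$g + rnorm(300, 0, 0.002)
  good_s <- f1 * pa$s + (1 - f1) * pb$s + rnorm(300, 0, 0.002)
  junk <- cbind(runif(100, 0.05, 0.2), runif(100, 0.05, 0.15))
  cloud <- c(lapply(seq_len(300), function(i)
    phasor(good_g[i], good_s[i], 1, ax$frequency_MHz)),
    lapply(seq_len(100), function(i)
      phasor(junk[i, 1], junk[i, 2], 1, ax$frequency_MHz)))
  region <- phasor_roi(vertices = cbind(c(0.2, 0.95, 0.95, 0.2),
                                        c(0.25, 0.25, 0.55, 0.55)),
                       name = "chord band")
  refs <- principal_axis_uc_references(cloud, selection = region)
  expect_lt(abs(refs$tau1_ns - 1) / 1, 0.05)
  expect_lt(abs(refs$tau2_ns - 3) / 3, 0.05)
  expect_match(refs$message, "chord band")

  # unrestricted fit on the contaminated cloud must differ
  refs_all <- principal_axis_uc_references(cloud)
  expect_gt(abs(refs_all$tau2_ns - refs$tau2_ns), 0.01)
})

test_that("equal weights reproduce the unweighted axis", {
  ax <- ax_default()
  set.seed(29)
  f1 <- runif(50)
  pa <- uc_phasor(0.8, axis = ax); pb <- uc_phasor(3.5, axis = ax)
  cloud <- lapply(seq_len(50), function(i)
    phasor(f1[i] * pa$g + (1 - f1[i]) * pb$g,
           f1[i] * pa$s + (1 - f1[i]) * pb$s, 1, ax$frequency_MHz))
  r1 <- principal_axis_uc_references(cloud)
  r2 <- principal_axis_uc_references(cloud, weights = rep(2, 50))
  expect_equal(r1$tau1_ns, r2$tau1_ns, tolerance = 1e-12)
  expect_equal(r1$tau2_ns, r2$tau2_ns, tolerance = 1e-12)
})

test_that("decomposition projects onto the reference segment with clamping", {
  ax <- ax_default()
  refs <- reference_pair(uc_phasor(1, axis = ax), uc_phasor(3, axis = ax),
                         1, 3)
  d1 <- decompose_phasor(refs$p1, refs)
  expect_equal(d1$f1, 1)
  expect_equal(d1$residual, 0)

  mid <- phasor((refs$p1$g + refs$p2$g) / 2, (refs$p1$s + refs$p2$s) / 2,
                1, ax$frequency_MHz)
  expect_equal(decompose_phasor(mid, refs)$f1, 0.5, tolerance = 1e-12)

  over <- phasor(refs$p2$g + 1.2 * (refs$p1$g - refs$p2$g),
                 refs$p2$s + 1.2 * (refs$p1$s - refs$p2$s),
                 1, ax$frequency_MHz)
  do <- decompose_phasor(over, refs)
  expect_equal(do$f1_raw, 1.2, tolerance = 1e-12)
  expect_equal(do$f1, 1)
  expect_true(do$clamped)

  # f1 + f2 = 1 always, residual >= 0
  set.seed(37)
  for (i in 1:20) {
    p <- phasor(runif(1), runif(1, 0, 0.6), 1, ax$frequency_MHz)
    dc <- decompose_phasor(p, refs)
    expect_identical(dc$f1 + dc$f2, 1)
    expect_gte(dc$residual, 0)
  }

  far <- phasor(0.5, 0.05, 1, ax$frequency_MHz)
  expect_false(decompose_phasor(far, refs, max_residual = 0.01)$valid)
  expect_true(decompose_phasor(mid, refs, max_residual = 0.01)$valid)
})

test_that("amplitude-averaged lifetime follows the closed form", {
  ax <- ax_default()
  refs <- reference_pair(uc_phasor(1, axis = ax), uc_phasor(3, axis = ax),
                         1, 3)
  expect_equal(amplitude_avg_lifetime(1, refs), 1)
  expect_equal(amplitude_avg_lifetime(0, refs), 3)
  expect_equal(amplitude_avg_lifetime(0.5, refs), 1 / (0.5 + 1 / 6))
  expect_equal(amplitude_avg_lifetime(0.5, refs), 1.5)

  same <- reference_pair(uc_phasor(2, axis = ax), uc_phasor(2, axis = ax),
                         2, 2)
  for (f1 in c(0, 0.3, 1))
    expect_equal(amplitude_avg_lifetime(f1, same), 2)
})

test_that("noiseless mixtures recover fractions and lifetime end to end", {
  ax <- time_axis(4096, frequency_MHz = 78.02)
  irf <- gauss_irf(ax)
  cal <- phasor_calibration(decay_phasor(irf, ax), 0)
  refs <- reference_pair(uc_phasor(0.8, axis = ax),
                         uc_phasor(3.5, axis = ax), 0.8, 3.5)
  for (f1 in c(0.2, 0.5, 0.85)) {
    amps <- c(f1 / 0.8, (1 - f1) / 3.5)    # intensity fractions -> amplitudes
    d <- simulate_decay(amps, c(0.8, 3.5), irf = irf, axis = ax,
                        total_counts = 1e6, noiseless = TRUE)
    pc <- calibrate(decay_phasor(d, ax), cal)
    dc <- decompose_phasor(pc, refs)
    expect_lt(abs(dc$f1 - f1), 1e-6)
    tau_a <- amplitude_avg_lifetime(dc, refs)
    expect_equal(tau_a, truth_tau_avg(amps, c(0.8, 3.5)), tolerance = 1e-3)
  }
})

test_that("phasor-plot regions select the matching image pixels", {
  ax <- ax_default()
  # two-population scene: cells in two lifetime groups
  sc <- simulate_scene(
    n_cells = 8, shape = c(64, 64), seed = 14, counts_per_cell = 4e5,
    lifetime_populations = list(
      list(tau1_ns = 0.9, tau2_ns = 1.1, a1_fraction = 0.5, a1_jitter = 0,
           weight = 1),
      list(tau1_ns = 3.2, tau2_ns = 3.8, a1_fraction = 0.5, a1_jitter = 0,
           weight = 1)),
    axis = ax, irf = gauss_irf(ax))
  pops <- vapply(sc$truth$cells, `[[`, integer(1), "population")
  # need both populations present
  expect_true(all(c(1, 2) %in% pops))
  vm <- validity_mask(sc$dataset, 100)
  pim <- calibrate(phasor_image(sc$dataset, mask = vm),
                   phasor_calibration(decay_phasor(sc$truth$irf, ax), 0))

  whole <- phasor_roi(vertices = cbind(c(-2, 2, 2, -2), c(-2, -2, 2, 2)))
  sel_all <- phasor_select(pim, whole)
  expect_true(all(unclass(sel_all) == unclass(pim$valid)))

  p_short <- uc_phasor(1, axis = ax)   # population-1 phasors cluster here
  disc <- phasor_roi(center = c(p_short$g, p_short$s), radius = 0.08)
  sel <- phasor_select(pim, disc)
  truth_pix <- matrix(FALSE, 64, 64)
  for (cell in sc$truth$cells[pops == 1]) {
    idx <- cell$pixels[, 1] + 1L + 64L * cell$pixels[, 2]
    truth_pix[idx] <- TRUE
  }
  truth_pix <- truth_pix & unclass(vm)
  mismatch <- sum(xor(unclass(sel), truth_pix)) / sum(truth_pix)
  expect_lt(mismatch, 0.05)

  expect_error(phasor_roi(vertices = cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
})
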