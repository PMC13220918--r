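#' Synthetic Gaussian instrument response function
#'
#' A Gaussian IRF sampled at the bin centers and wrapped periodically over
#' the laser period, normalized to a stated total count. The
#' delta-function limit (`fwhm -> 0`) concentrates all mass in one bin.
#'
#' @param axis an [time_axis()].
#' @param center_ns peak position in ns.
#' @param fwhm_ns full width at half maximum in ns (> 0).
#' @param total_counts total counts of the returned curve.
#' @return An [decay_curve()].
#' @export
make_irf <- function(axis, center_ns, fwhm_ns, total_counts = 1e6) {
  stopifnot(inherits(axis, "fli_time_axis"))
  if (fwhm_ns <= 0) stop("'fwhm_ns' must be positive")
  sg <- fwhm_ns / (2 * sqrt(2 * log(2)))
  t <- axis$bin_centers_ns
  T <- axis$period_ns
  y <- numeric(axis$n_bins)
  for (k in -3:3) y <- y + stats::dnorm(t + k * T, center_ns, sg)
  if (sum(y) == 0) {
    # narrower than the grid can resolve: all mass in the nearest bin
    y[which.min(abs(t - center_ns))] <- 1
  }
  y <- y / sum(y) * total_counts
  decay_curve(t, y)
}

#' Delta-function IRF on a time axis
#'
#' All counts in the bin containing `center_ns` — useful when the model
#' should reduce to the bare wrapped exponential.
#'
#' @param axis an [time_axis()].
#' @param center_ns position (default: first bin).
#' @param total_counts total counts.
#' @return An [decay_curve()].
#' @export
delta_irf <- function(axis, center_ns = NULL, total_counts = 1e6) {
  y <- numeric(axis$n_bins)
  k <- if (is.null(center_ns)) 1L
       else which.min(abs(axis$bin_centers_ns - center_ns))
  y[k] <- total_counts
  decay_curve(axis$bin_centers_ns, y)
}

#' Simulate a single decay curve
#'
#' Evaluates the reconvolution forward model ([model_decay()]), rescales it
#' to a requested total count, and applies independent per-bin Poisson
#' draws. With a fixed seed the output is bit-reproducible; `noiseless =
#' TRUE` returns the expectation itself.
#'
#' @param amplitudes,lifetimes_ns,background decay truth (see
#'   [decay_params()]); `background` is in counts/bin before rescaling.
#' @param irf an [decay_curve()] IRF.
#' @param axis the [time_axis()].
#' @param total_counts requested expected total (> 0).
#' @param seed RNG seed (ignored when `noiseless`).
#' @param shift_ns IRF shift applied in the model.
#' @param noiseless skip the Poisson noise.
#' @return An [decay_curve()].
#' @export
simulate_decay <- function(amplitudes, lifetimes_ns, background = 0,
                           irf, axis, total_counts, seed = 1L,
                           shift_ns = 0, noiseless = FALSE) {
  if (total_counts <= 0) stop("'total_counts' must be positive")
  pars <- decay_params(amplitudes, lifetimes_ns, background, shift_ns)
  m <- model_decay(pars, irf, axis)
  m <- m / sum(m) * total_counts
  if (noiseless) return(decay_curve(axis$bin_centers_ns, m))
  set.seed(as.integer(seed))
  decay_curve(axis$bin_centers_ns, stats::rpois(length(m), m))
}

#' Closed-form amplitude-averaged lifetime of a bi-exponential truth
#'
#' `<tau>_a = sum(a_i tau_i) / sum(a_i)` — the quantity the phasor
#' decomposition pipeline should recover.
#'
#' @param amplitudes,lifetimes_ns component truth.
#' @return `<tau>_a` in ns.
#' @export
truth_tau_avg <- function(amplitudes, lifetimes_ns) {
  sum(amplitudes * lifetimes_ns) / sum(amplitudes)
}

place_ellipses <- function(n_cells, shape, rng, max_tries = 200L) {
  # rejection placement of non-overlapping axis-aligned ellipses
  occupied <- matrix(FALSE, shape[1], shape[2])
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ra <- stats::runif(1, rng$semi_axes[1], rng$semi_axes[2])
      rb <- stats::runif(1, rng$semi_axes[1], rng$semi_axes[2])
      th <- stats::runif(1, 0, pi)
      cr <- stats::runif(1, ra + 1, shape[1] - ra - 1)
      cc <- stats::runif(1, rb + 1, shape[2] - rb - 1)
      rr <- floor(max(cr - ra - rb, 1)):ceiling(min(cr + ra + rb, shape[1]))
      cc2 <- floor(max(cc - ra - rb, 1)):ceiling(min(cc + ra + rb, shape[2]))
      grid <- expand.grid(row = rr, col = cc2)
      dx <- grid$row - cr; dy <- grid$col - cc
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / ra)^2 + (v / rb)^2 <= 1
      px <- grid[inside, , drop = FALSE]
      if (nrow(px) < 3L) next
      idx <- px$row + shape[1] * (px$col - 1L)
      if (any(occupied[idx])) next
      occupied[idx] <- TRUE
      cells[[i]] <- cbind(row = as.integer(px$row - 1L),
                          col = as.integer(px$col - 1L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           shape[1], " x ", shape[2], " frame after ", max_tries,
           " tries each")
  }
  cells
}

#' Simulate a field of cell-shaped ROIs with bi-exponential decays
#'
#' Emulates a voltage-sensitive-dye FLIM field of view: non-overlapping
#' ellipsoidal "cells" on a dark background, each carrying a
#' bi-exponential decay drawn from one of the given lifetime populations,
#' convolved with a (optionally per-pixel shifted) IRF and subjected to
#' Poisson counting noise. Returns the dataset, the matching label mask and
#' the full ground truth, so every downstream stage can be checked against
#' what was put in.
#'
#' Defaults reproduce the bacterial-membrane-potential acquisition
#' geometry: 78.02 MHz repetition rate, 256 time bins, a 0.4 ns FWHM
#' Gaussian IRF centered at 1 ns, and a single population with lifetimes
#' 1 and 3.5 ns mixed 60/40 by amplitude (with a cell-to-cell
#' amplitude-fraction jitter of sd 0.05, the kind of population
#' heterogeneity a voltage-sensitive-dye experiment shows), 1e5 expected
#' counts per cell.
#'
#' @param n_cells number of cells.
#' @param shape image `c(rows, cols)`.
#' @param lifetime_populations list of populations, each a list with
#'   `tau1_ns`, `tau2_ns`, `a1_fraction` (amplitude fraction of component
#'   1), optional `a1_jitter` (sd of a per-cell jitter on the amplitude
#'   fraction, clipped to `[0.05, 0.95]`) and `weight`.
#' @param counts_per_cell expected total counts per cell.
#' @param axis the [time_axis()] (default 256 bins at 78.02 MHz).
#' @param irf the IRF (default 0.4 ns FWHM Gaussian at 1 ns).
#' @param seed RNG seed; every output is a pure function of seed +
#'   parameters.
#' @param per_pixel_shift optional function `(row, col) -> shift_ns`
#'   (0-based coordinates) emulating SPAD gate-position nonuniformity, or a
#'   `(rows, cols)` matrix of shifts.
#' @param background_rate expected background counts per bin per pixel.
#' @param cell_semi_axes range (pixels) the ellipse semi-axes are drawn
#'   from.
#' @param noiseless skip Poisson noise (expectations, rounded to nothing —
#'   real-valued cube).
#' @return List with `dataset` ([fli_dataset()]), `mask`
#'   (`fli_label_mask`) and `truth` (class `fli_scene_truth`): per-cell
#'   `pixels`, `amplitudes`, `lifetimes_ns`, `tau_avg_ns`, plus the global
#'   parameters and seed.
#' @export
simulate_scene <- function(n_cells = 20, shape = c(96, 96),
                           lifetime_populations = list(
                             list(tau1_ns = 1.0, tau2_ns = 3.5,
                                  a1_fraction = 0.6, a1_jitter = 0.05,
                                  weight = 1)),
                           counts_per_cell = 1e5,
                           axis = time_axis(256, frequency_MHz = 78.02),
                           irf = make_irf(axis, 1.0, 0.4),
                           seed = 1L, per_pixel_shift = NULL,
                           background_rate = 0, cell_semi_axes = c(3, 6),
                           noiseless = FALSE) {
  set.seed(as.integer(seed))
  shape <- as.integer(shape)
  cells <- place_ellipses(n_cells, shape,
                          list(semi_axes = cell_semi_axes))

  pw <- vapply(lifetime_populations, function(p) p$weight %||% 1, numeric(1))
  pop_of <- sample.int(length(lifetime_populations), n_cells, replace = TRUE,
                       prob = pw)

  shift_at <- NULL
  if (!is.null(per_pixel_shift)) {
    shift_at <- if (is.function(per_pixel_shift)) {
      outer(seq_len(shape[1]) - 1L, seq_len(shape[2]) - 1L, per_pixel_shift)
    } else as.matrix(per_pixel_shift)
    stopifnot(all(dim(shift_at) == shape))
  }

  nt <- axis$n_bins
  cube <- array(0, c(nt, shape[1], shape[2]))
  mask <- matrix(0L, shape[1], shape[2])
  truth_cells <- vector("list", n_cells)

  for (i in seq_len(n_cells)) {
    pop <- lifetime_populations[[pop_of[i]]]
    a1 <- pop$a1_fraction
    if (!is.null(pop$a1_jitter) && pop$a1_jitter > 0)
      a1 <- min(max(stats::rnorm(1, a1, pop$a1_jitter), 0.05), 0.95)
    amps <- c(a1, 1 - a1)
    taus <- c(pop$tau1_ns, pop$tau2_ns)
    px <- cells[[i]]
    npx <- nrow(px)
    per_px <- counts_per_cell / npx
    idx <- px[, 1] + 1L + shape[1] * px[, 2]
    mask[idx] <- i

    if (is.null(shift_at)) {
      pars <- decay_params(amps, taus)
      m <- model_decay(pars, irf, axis)
      m <- m / sum(m) * per_px
      for (j in seq_len(npx)) {
        lam <- m + background_rate
        cube[, px[j, 1] + 1L, px[j, 2] + 1L] <-
          if (noiseless) lam else stats::rpois(nt, lam)
      }
    } else {
      for (j in seq_len(npx)) {
        sh <- shift_at[px[j, 1] + 1L, px[j, 2] + 1L]
        pars <- decay_params(amps, taus, shift_ns = sh)
        m <- model_decay(pars, irf, axis)
        lam <- m / sum(m) * per_px + background_rate
        cube[, px[j, 1] + 1L, px[j, 2] + 1L] <-
          if (noiseless) lam else stats::rpois(nt, lam)
      }
    }
    truth_cells[[i]] <- list(
      id = i, pixels = px, population = pop_of[i],
      amplitudes = amps, lifetimes_ns = taus,
      tau_avg_ns = truth_tau_avg(amps, taus))
  }

  if (background_rate > 0 && !noiseless) {
    bgpix <- which(mask == 0L)
    for (j in bgpix) {
      rc <- arrayInd(j, shape)
      cube[, rc[1], rc[2]] <- stats::rpois(nt, background_rate)
    }
  } else if (background_rate > 0) {
    bg <- which(mask == 0L)
    for (j in bg) {
      rc <- arrayInd(j, shape)
      cube[, rc[1], rc[2]] <- background_rate
    }
  }

  truth <- structure(list(
    cells = truth_cells, axis = axis, irf = irf, seed = as.integer(seed),
    background_rate = background_rate,
    per_pixel_shift = shift_at), class = "fli_scene_truth")

  list(dataset = fli_dataset(cube, axis,
                             meta = list(source = "simulate_scene",
                                         seed = as.character(seed))),
       mask = structure(mask, class = "fli_label_mask"),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
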