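#' Decay model parameters
#'
#' Parameters of the reconvolution decay model: per-component pre-exponential
#' amplitudes `a_i` (counts/bin scale) and lifetimes `tau_i` (ns, canonical
#' order `tau1 < tau2`), a constant background `B` (counts/bin) and an IRF
#' time shift (ns, the "color shift" nuisance of reconvolution fitting).
#'
#' @param amplitudes numeric vector (length 1 or 2), all > 0.
#' @param lifetimes_ns numeric vector, same length, all > 0.
#' @param background `B >= 0`.
#' @param shift_ns IRF shift in ns.
#' @return An object of class `fli_decay_params`.
#' @export
decay_params <- function(amplitudes, lifetimes_ns, background = 0,
                         shift_ns = 0) {
  if (length(amplitudes) != length(lifetimes_ns) ||
      !length(amplitudes) %in% 1:2)
    stop("need 1 or 2 components with matching amplitudes/lifetimes")
  if (any(lifetimes_ns <= 0)) stop("lifetimes must be positive")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (background < 0) stop("background must be >= 0")
  o <- order(lifetimes_ns)
  structure(list(amplitudes = as.numeric(amplitudes[o]),
                 lifetimes_ns = as.numeric(lifetimes_ns[o]),
                 background = as.numeric(background),
                 shift_ns = as.numeric(shift_ns)),
            class = "fli_decay_params")
}

# circular shift of a curve by `shift_ns` (positive = delay) using periodic
# linear interpolation on a uniform grid
shift_periodic <- function(y, shift_ns, dt) {
  n <- length(y)
  sb <- shift_ns / dt
  i0 <- floor(sb)
  fr <- sb - i0
  idx <- function(k) ((k - 1L) %% n) + 1L
  k <- seq_len(n)
  (1 - fr) * y[idx(k - i0)] + fr * y[idx(k - i0 - 1L)]
}

#' Reconvolution forward model
#'
#' Expected counts per bin under periodic excitation: the wrapped
#' multi-exponential `sum_i a_i exp(-t/tau_i) / (1 - exp(-T/tau_i))`
#' (steady-state solution over laser period `T`), circularly convolved with
#' the unit-normalized, shift-interpolated IRF, plus the constant
#' background. The exponential is evaluated on the lag grid with the
#' half-weight first-channel convention at its wrap discontinuity, which
#' makes the discrete convolution reproduce the continuous reconvolution
#' integral to spectral accuracy (so modeled-data phasors factor exactly
#' into IRF phasor times decay phasor). With a delta IRF and `B = 0` the
#' model reduces to the wrapped exponential itself.
#'
#' @param params an [decay_params()].
#' @param irf an [decay_curve()] on the same (uniform) time grid; total > 0.
#' @param axis the [time_axis()].
#' @return Numeric vector of expected counts per bin (all >= 0).
#' @export
model_decay <- function(params, irf, axis) {
  stopifnot(inherits(params, "fli_decay_params"),
            inherits(irf, "fli_decay"), inherits(axis, "fli_time_axis"))
  if (sum(irf$counts) <= 0) stop("IRF has zero total counts")
  if (length(irf$counts) != axis$n_bins)
    stop("IRF must be sampled on the axis grid")
  if (!is_uniform_axis(axis))
    stop("model_decay requires a uniform time grid")
  n <- axis$n_bins
  T <- axis$period_ns
  dt <- T / n
  dec <- wrapped_exp_lags(params$amplitudes, params$lifetimes_ns, n, T)
  h <- irf$counts / sum(irf$counts)
  h <- shift_periodic(h, params$shift_ns, dt)
  m <- Re(stats::fft(stats::fft(dec) * stats::fft(h), inverse = TRUE)) / n
  pmax(m + params$background, 0)
}

# Wrapped multi-exponential evaluated on the lag grid m*dt, m = 0..n-1,
# with the half-weight (jump-midpoint) value at lag 0.  This is the kernel
# whose circular convolution with a center-sampled IRF reproduces the
# continuous reconvolution integral to spectral accuracy, so the phasor of
# the modeled data equals the product of the IRF and decay phasors (the
# property IRF calibration relies on).
wrapped_exp_lags <- function(amplitudes, lifetimes_ns, n, T) {
  dt <- T / n
  lag <- (0:(n - 1)) * dt
  dec <- numeric(n)
  for (i in seq_along(amplitudes)) {
    tau <- lifetimes_ns[i]
    q <- exp(-T / tau)
    comp <- amplitudes[i] * exp(-lag / tau) / (1 - q)
    comp[1] <- amplitudes[i] * (1 + q) / (2 * (1 - q))
    dec <- dec + comp
  }
  dec
}

fit_par_pack <- function(params, fit_background, fit_shift) {
  p <- c(params$amplitudes, params$lifetimes_ns)
  if (fit_background) p <- c(p, params$background)
  if (fit_shift) p <- c(p, params$shift_ns)
  p
}

fit_par_unpack <- function(p, ncomp, fit_background, fit_shift, fixed) {
  a <- p[seq_len(ncomp)]
  tau <- p[ncomp + seq_len(ncomp)]
  i <- 2 * ncomp
  B <- if (fit_background) p[i <- i + 1] else fixed$background
  sh <- if (fit_shift) p[i + 1] else fixed$shift_ns
  list(amplitudes = a, lifetimes_ns = tau, background = B, shift_ns = sh)
}

# raw (unordered) parameter list -> model curve; avoids decay_params()
# overhead and reordering inside the optimizer loop
model_raw <- function(pl, irf_n, t, T, dt, n) {
  dec <- wrapped_exp_lags(pl$amplitudes, pmax(pl$lifetimes_ns, 1e-6), n, T)
  h <- shift_periodic(irf_n, pl$shift_ns, dt)
  m <- Re(stats::fft(stats::fft(dec) * stats::fft(h), inverse = TRUE)) / n
  pmax(m + pl$background, 0)
}

default_fit_init <- function(counts, t, T, dt, ncomp) {
  B0 <- max(min(counts), 0)
  kp <- which.max(counts)
  y <- counts - B0
  tail_idx <- seq(kp, length(counts))
  use <- tail_idx[y[tail_idx] > max(1, sqrt(B0))]
  tau0 <- NA_real_
  if (length(use) >= 5L) {
    fitl <- stats::lm(log(y[use] + 0.5) ~ t[use])
    sl <- stats::coef(fitl)[2]
    if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
  }
  if (!is.finite(tau0)) tau0 <- T / 5
  tau0 <- min(max(tau0, 0.01), 0.8 * T)
  A <- max(sum(y), 1)
  if (ncomp == 1L) {
    decay_params(A * dt / tau0, tau0, background = B0, shift_ns = 0)
  } else {
    taus <- c(tau0 / 2, tau0 * 2)
    decay_params(A * dt / (2 * taus), taus, background = B0, shift_ns = 0)
  }
}

#' Fit an exponential decay by iterative reconvolution
#'
#' Fits the [model_decay()] reconvolution model to a measured decay by one
#' of three estimators:
#' * `"nlsf_unweighted"` — least squares on raw residuals,
#'   `sum (n_k - m_k)^2`;
#' * `"nlsf_weighted"` — chi-square with Neyman weights,
#'   `sum (n_k - m_k)^2 / max(n_k, 1)` (standard TCSPC practice);
#' * `"mle"` — Poisson maximum likelihood, minimizing the deviance
#'   `2 sum(m_k - n_k + n_k log(n_k / m_k))` (terms with `n_k = 0`
#'   contribute `m_k`).
#'
#' Least-squares fits use Levenberg-Marquardt with box bounds
#' (`tau` in `[1e-3, 1e3]` ns, `a, B >= 0`, `|shift| <= T/2`); the MLE is a
#' bounded quasi-Newton refinement started from the weighted-NLSF optimum.
#' Initialization is deterministic (log-linear regression on the decay
#' tail); two-component starts split the single-lifetime estimate by
#' x/2 and x2. Non-convergence is reported via the `converged` flag, not an
#' error.
#'
#' @param d an [decay_curve()] of the measured data.
#' @param irf an [decay_curve()] IRF on the same grid.
#' @param axis the [time_axis()].
#' @param n_components 1 or 2.
#' @param method `"nlsf_weighted"` (default), `"nlsf_unweighted"` or
#'   `"mle"`.
#' @param init optional [decay_params()] starting values.
#' @param fit_range optional integer vector of time-bin indices entering
#'   the objective (the model is always computed over the full period).
#' @param fit_background,fit_shift free/frozen flags for `B` and the IRF
#'   shift (both fitted by default).
#' @return An object of class `decay_fit`: fields `params`
#'   ([decay_params()], canonical lifetime order), `chi2_reduced` (Neyman
#'   reduced chi-square over the fit range), `deviance`,
#'   `neg_log_likelihood`, `cov` (covariance estimate or NULL), `n_iter`,
#'   `converged`, `method`, plus the inputs needed by its methods.
#' @seealso [predict.decay_fit()], [residuals.decay_fit()],
#'   [simulate.decay_fit()]
#' @export
fit_decay <- function(d, irf, axis, n_components = 1L,
                      method = c("nlsf_weighted", "nlsf_unweighted", "mle"),
                      init = NULL, fit_range = NULL,
                      fit_background = TRUE, fit_shift = TRUE) {
  stopifnot(inherits(d, "fli_decay"), inherits(irf, "fli_decay"),
            inherits(axis, "fli_time_axis"))
  method <- match.arg(method)
  ncomp <- as.integer(n_components)
  if (!ncomp %in% 1:2) stop("'n_components' must be 1 or 2")
  n <- axis$n_bins
  if (length(d$counts) != n) stop("decay length does not match the axis")
  if (sum(d$counts) <= 0) stop("empty decay: zero total counts")
  if (sum(irf$counts) <= 0) stop("IRF has zero total counts")
  counts <- d$counts
  t <- axis$bin_centers_ns
  T <- axis$period_ns
  dt <- T / n
  irf_n <- irf$counts / sum(irf$counts)
  win <- if (is.null(fit_range)) seq_len(n) else as.integer(fit_range)
  if (any(win < 1L) || any(win > n)) stop("'fit_range' out of bounds")

  if (is.null(init)) init <- default_fit_init(counts, t, T, dt, ncomp)
  else if (!inherits(init, "fli_decay_params")) stop("invalid 'init'")
  if (length(init$amplitudes) != ncomp)
    stop("'init' has ", length(init$amplitudes), " components, need ", ncomp)

  fixed <- list(background = init$background, shift_ns = init$shift_ns)
  p0 <- fit_par_pack(init, fit_background, fit_shift)
  lower <- c(rep(0, ncomp), rep(1e-3, ncomp))
  upper <- c(rep(Inf, ncomp), rep(1e3, ncomp))
  if (fit_background) { lower <- c(lower, 0); upper <- c(upper, Inf) }
  if (fit_shift) { lower <- c(lower, -T / 2); upper <- c(upper, T / 2) }
  nfree <- length(p0)
  dof <- max(length(win) - nfree, 1L)

  model_of <- function(p) {
    pl <- fit_par_unpack(p, ncomp, fit_background, fit_shift, fixed)
    model_raw(pl, irf_n, t, T, dt, n)
  }
  wres <- sqrt(pmax(counts[win], 1))
  resid_fun <- if (method == "nlsf_unweighted") {
    function(p) counts[win] - model_of(p)[win]
  } else {
    function(p) (counts[win] - model_of(p)[win]) / wres
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     gtol = 1e-10, maxiter = 500,
                                     maxfev = 20000)
  lm <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                           fn = resid_fun, control = ctrl)
  p_hat <- lm$par
  n_iter <- lm$niter
  converged <- lm$info %in% 1:4

  if (method == "mle") {
    devi <- function(p) {
      m <- pmax(model_of(p)[win], 1e-12)
      nn <- counts[win]
      pos <- nn > 0
      2 * (sum(m - nn) + sum(nn[pos] * log(nn[pos] / m[pos])))
    }
    op <- stats::optim(p_hat, devi, method = "L-BFGS-B",
                       lower = lower, upper = pmin(upper, 1e12),
                       control = list(factr = 10, pgtol = 1e-12,
                                      maxit = 500))
    p_hat <- op$par
    n_iter <- n_iter + op$counts[1]
    converged <- converged && op$convergence %in% c(0, 52)
  }

  pl <- fit_par_unpack(p_hat, ncomp, fit_background, fit_shift, fixed)
  params <- decay_params(pmax(pl$amplitudes, 0), pl$lifetimes_ns,
                         background = max(pl$background, 0),
                         shift_ns = pl$shift_ns)
  m_hat <- model_of(p_hat)
  chi2 <- sum((counts[win] - m_hat[win])^2 / pmax(counts[win], 1))
  mm <- pmax(m_hat[win], 1e-12)
  nn <- counts[win]
  pos <- nn > 0
  devi_val <- 2 * (sum(mm - nn) + sum(nn[pos] * log(nn[pos] / mm[pos])))

  cov <- tryCatch({
    J <- lm$hessian          # J'J approximation from nls.lm (weighted)
    s2 <- chi2 / dof
    V <- solve(J) * if (method == "nlsf_unweighted") 2 * lm$deviance / dof
                    else 2 * s2
    V
  }, error = function(e) NULL)

  structure(list(params = params, chi2_reduced = chi2 / dof,
                 deviance = devi_val, neg_log_likelihood = devi_val / 2,
                 cov = cov, n_iter = n_iter, converged = converged,
                 method = method, dof = dof, fit_range = win,
                 data = d, irf = irf, axis = axis,
                 fit_background = fit_background, fit_shift = fit_shift),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  p <- x$params
  comp <- paste(sprintf("tau%d = %.4g ns (a%d = %.4g)",
                        seq_along(p$lifetimes_ns), p$lifetimes_ns,
                        seq_along(p$amplitudes), p$amplitudes),
                collapse = ", ")
  cat(sprintf("<decay_fit> %s, %d component(s)\n  %s\n", x$method,
              length(p$lifetimes_ns), comp))
  cat(sprintf("  B = %.4g, shift = %.4g ns, chi2_red = %.4g%s\n",
              p$background, p$shift_ns, x$chi2_reduced,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  p <- object$params
  nc <- length(p$lifetimes_ns)
  stats::setNames(
    c(p$amplitudes, p$lifetimes_ns, p$background, p$shift_ns),
    c(paste0("a", seq_len(nc)), paste0("tau", seq_len(nc)), "B", "shift"))
}

#' @export
summary.decay_fit <- function(object, ...) {
  se <- if (!is.null(object$cov)) sqrt(pmax(diag(object$cov), 0)) else NULL
  out <- list(coefficients = coef(object), se = se,
              chi2_reduced = object$chi2_reduced,
              deviance = object$deviance, dof = object$dof,
              method = object$method, converged = object$converged,
              n_iter = object$n_iter)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit (%s), %s\n", x$method,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients)
  cat(sprintf("reduced chi2 = %.5g on %d dof; deviance = %.5g; %d iter\n",
              x$chi2_reduced, x$dof, x$deviance, x$n_iter))
  invisible(x)
}

#' Predicted decay of a fit
#'
#' @param object a [fit_decay()] result.
#' @param ... unused.
#' @return Numeric vector of fitted counts per bin.
#' @export
predict.decay_fit <- function(object, ...) {
  model_decay(object$params, object$irf, object$axis)
}

#' Residuals of a decay fit
#'
#' @param object a [fit_decay()] result.
#' @param type `"raw"` (`n - m`), `"pearson"` (Neyman-weighted) or
#'   `"deviance"`.
#' @param ... unused.
#' @return Numeric vector over the fit range.
#' @export
residuals.decay_fit <- function(object, type = c("raw", "pearson",
                                                 "deviance"), ...) {
  type <- match.arg(type)
  w <- object$fit_range
  nn <- object$data$counts[w]
  m <- predict(object)[w]
  switch(type,
         raw = nn - m,
         pearson = (nn - m) / sqrt(pmax(nn, 1)),
         deviance = {
           m <- pmax(m, 1e-12)
           term <- m - nn + ifelse(nn > 0, nn * log(nn / m), 0)
           sign(nn - m) * sqrt(2 * pmax(term, 0))
         })
}

#' Simulate replicate decays from a fit
#'
#' Poisson draws around the fitted curve — parametric bootstrap material.
#'
#' @param object a [fit_decay()] result.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of [decay_curve()]s of length `nsim`.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- predict(object)
  lapply(seq_len(nsim), function(i)
    decay_curve(object$axis$bin_centers_ns, stats::rpois(length(m), m)))
}

#' Pixel-wise decay fitting over an image
#'
#' Runs [fit_decay()] independently at every valid pixel (optionally with a
#' per-pixel IRF cube, the SPAD-camera case) and assembles parameter maps.
#' All pixels share a deterministic initialization derived from the global
#' (summed) decay, so results do not depend on pixel order.
#'
#' @param ds an [fli_dataset()].
#' @param irf an [decay_curve()], or a 3-D array `(time, row, col)` of
#'   per-pixel IRFs matching the dataset shape.
#' @param n_components,method,fit_background,fit_shift as in [fit_decay()].
#' @param mask optional [validity_mask()]; default: pixels with any counts.
#' @return A list of class `fli_fit_image`: `maps` (named list of matrices:
#'   `tau1`, `a1`, (`tau2`, `a2`,) `background`, `shift_ns`,
#'   `chi2_reduced`), `converged` (logical matrix) and `mask`.
#' @export
fit_image <- function(ds, irf, n_components = 1L,
                      method = "nlsf_weighted", mask = NULL,
                      fit_background = TRUE, fit_shift = TRUE) {
  stopifnot(inherits(ds, "fli_dataset"))
  d <- dim(ds$counts)
  axis <- ds$time_axis
  if (is.null(mask)) mask <- validity_mask(ds, min_counts = 1)
  per_pixel_irf <- is.array(irf) && length(dim(irf)) == 3L
  if (per_pixel_irf && !all(dim(irf) == d))
    stop("per-pixel IRF cube must match the dataset dimensions")
  if (!per_pixel_irf && !inherits(irf, "fli_decay"))
    stop("'irf' must be a decay curve or a per-pixel IRF cube")

  # shared deterministic init from the global decay, scaled per pixel
  glob <- decay_curve(axis$bin_centers_ns, rowSums(matrix(ds$counts, d[1])))
  ginit <- default_fit_init(glob$counts, axis$bin_centers_ns, axis$period_ns,
                            axis$period_ns / d[1], as.integer(n_components))

  nm <- c(paste0("a", seq_len(n_components)),
          paste0("tau", seq_len(n_components)), "background", "shift_ns",
          "chi2_reduced")
  maps <- stats::setNames(
    replicate(length(nm), matrix(NA_real_, d[2], d[3]), simplify = FALSE), nm)
  conv <- matrix(FALSE, d[2], d[3])
  gtot <- sum(glob$counts)

  for (idx in which(unclass(mask))) {
    rc <- arrayInd(idx, c(d[2], d[3]))
    y <- ds$counts[, rc[1], rc[2]]
    if (sum(y) <= 0) next
    scl <- sum(y) / gtot
    ini <- decay_params(ginit$amplitudes * scl, ginit$lifetimes_ns,
                        background = ginit$background * scl, shift_ns = 0)
    pirf <- if (per_pixel_irf)
      decay_curve(axis$bin_centers_ns, irf[, rc[1], rc[2]]) else irf
    ft <- tryCatch(
      fit_decay(decay_curve(axis$bin_centers_ns, y), pirf, axis,
                n_components = n_components, method = method, init = ini,
                fit_background = fit_background, fit_shift = fit_shift),
      error = function(e) NULL)
    if (is.null(ft)) next
    p <- ft$params
    for (i in seq_len(n_components)) {
      maps[[paste0("a", i)]][idx] <- p$amplitudes[i]
      maps[[paste0("tau", i)]][idx] <- p$lifetimes_ns[i]
    }
    maps$background[idx] <- p$background
    maps$shift_ns[idx] <- p$shift_ns
    maps$chi2_reduced[idx] <- ft$chi2_reduced
    conv[idx] <- ft$converged
  }
  structure(list(maps = maps, converged = conv, mask = mask,
                 method = method, n_components = n_components),
            class = "fli_fit_image")
}
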