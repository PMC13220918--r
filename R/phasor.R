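#' Phasor of a decay
#'
#' A point `(g, s)` in phasor space: the normalized cosine and sine Fourier
#' components of a decay at harmonic `n` of the laser repetition frequency.
#' Single-exponential decays fall on the universal circle; mixtures fall
#' inside it on chords between their components.
#'
#' @param g,s phasor coordinates (finite).
#' @param harmonic positive integer harmonic.
#' @param frequency_MHz repetition frequency in MHz.
#' @return An object of class `fli_phasor`.
#' @export
phasor <- function(g, s, harmonic = 1L, frequency_MHz) {
  if (!is.finite(g) || !is.finite(s)) stop("phasor coordinates must be finite")
  if (harmonic < 1) stop("'harmonic' must be >= 1")
  structure(list(g = as.numeric(g), s = as.numeric(s),
                 harmonic = as.integer(harmonic),
                 frequency_MHz = as.numeric(frequency_MHz)),
            class = "fli_phasor")
}

#' @export
print.fli_phasor <- function(x, ...) {
  cat(sprintf("<fli_phasor> g = %.6g, s = %.6g (n = %d, f = %.6g MHz)\n",
              x$g, x$s, x$harmonic, x$frequency_MHz))
  invisible(x)
}

phasor_z <- function(p) complex(real = p$g, imaginary = p$s)

phasor_omega <- function(p) 2 * pi * p$harmonic * p$frequency_MHz * 1e-3  # 1/ns

#' Phasor of a decay curve
#'
#' Discrete phasor over bin centers `t_k` with `omega = 2*pi*n/T`:
#' `g = sum(c_k cos(omega t_k)) / sum(c_k)`,
#' `s = sum(c_k sin(omega t_k)) / sum(c_k)`.
#' This is the raw (uncalibrated) phasor; apply [calibrate()] with an IRF
#' or known-lifetime reference before interpreting it.
#'
#' @param d an [decay_curve()].
#' @param axis the [time_axis()] defining period and frequency.
#' @param harmonic harmonic `n` (default 1).
#' @return An [phasor()].
#' @export
decay_phasor <- function(d, axis, harmonic = 1L) {
  stopifnot(inherits(d, "fli_decay"), inherits(axis, "fli_time_axis"))
  tot <- sum(d$counts)
  if (tot <= 0) stop("empty decay: zero total counts")
  w <- angular_frequency(axis, harmonic)
  t <- d$time_ns
  phasor(sum(d$counts * cos(w * t)) / tot,
         sum(d$counts * sin(w * t)) / tot,
         harmonic, axis$frequency_MHz)
}

#' Construct a phasor image
#'
#' @param g,s numeric matrices of phasor coordinates.
#' @param valid logical matrix (or `fli_validity_mask`) of the same shape.
#' @param harmonic,frequency_MHz as in [phasor()].
#' @return An object of class `fli_phasor_image`.
#' @export
phasor_image_new <- function(g, s, valid, harmonic, frequency_MHz) {
  stopifnot(is.matrix(g), is.matrix(s), all(dim(g) == dim(s)),
            all(dim(g) == dim(valid)))
  structure(list(g = g, s = s, valid = valid,
                 harmonic = as.integer(harmonic),
                 frequency_MHz = as.numeric(frequency_MHz)),
            class = "fli_phasor_image")
}

#' @export
print.fli_phasor_image <- function(x, ...) {
  cat(sprintf("<fli_phasor_image> %d x %d (%d valid), n = %d, f = %.6g MHz\n",
              nrow(x$g), ncol(x$g), sum(x$valid), x$harmonic, x$frequency_MHz))
  invisible(x)
}

#' Pixel-wise phasor image of a dataset
#'
#' [decay_phasor()] applied at every valid pixel; invalid pixels carry `NA`.
#'
#' @param ds an [fli_dataset()].
#' @param harmonic harmonic `n` (default 1).
#' @param mask optional [validity_mask()]; default: pixels with any counts.
#' @return An `fli_phasor_image`.
#' @export
phasor_image <- function(ds, harmonic = 1L, mask = NULL) {
  stopifnot(inherits(ds, "fli_dataset"))
  d <- dim(ds$counts)
  if (is.null(mask)) mask <- validity_mask(ds, min_counts = 1)
  w <- angular_frequency(ds$time_axis, harmonic)
  t <- ds$time_axis$bin_centers_ns
  flat <- matrix(ds$counts, nrow = d[1])         # bins x pixels
  tot <- colSums(flat)
  gv <- colSums(flat * cos(w * t)) / tot
  sv <- colSums(flat * sin(w * t)) / tot
  gm <- matrix(gv, d[2], d[3])
  sm <- matrix(sv, d[2], d[3])
  ok <- unclass(mask) & tot > 0
  gm[!ok] <- NA_real_
  sm[!ok] <- NA_real_
  phasor_image_new(gm, sm, ok, harmonic, ds$time_axis$frequency_MHz)
}

#' Phasor calibration
#'
#' A calibration phasor of known lifetime `tau_ref` (0 ns for an IRF). In
#' `per_pixel` mode the payload is a phasor image (one calibration phasor
#' per pixel, as needed for SPAD cameras with gate-position nonuniformity).
#'
#' @param phasor an [phasor()] (single mode) or `fli_phasor_image`
#'   (per-pixel mode).
#' @param reference_lifetime_ns lifetime of the calibration standard, >= 0.
#' @param mode `"single"` or `"per_pixel"`; inferred from the payload by
#'   default.
#' @return An object of class `fli_calibration`.
#' @export
phasor_calibration <- function(phasor, reference_lifetime_ns = 0,
                               mode = NULL) {
  if (is.null(mode))
    mode <- if (inherits(phasor, "fli_phasor_image")) "per_pixel" else "single"
  if (mode == "single" && !inherits(phasor, "fli_phasor"))
    stop("single mode needs a fli_phasor payload")
  if (mode == "per_pixel" && !inherits(phasor, "fli_phasor_image"))
    stop("per_pixel mode needs a fli_phasor_image payload")
  if (reference_lifetime_ns < 0) stop("'reference_lifetime_ns' must be >= 0")
  structure(list(mode = mode, phasor = phasor,
                 reference_lifetime_ns = as.numeric(reference_lifetime_ns)),
            class = "fli_calibration")
}

#' Calibrate a phasor or phasor image
#'
#' Complex division by the calibration phasor followed by multiplication by
#' the universal-circle phasor of the reference lifetime: moduli divide,
#' phases subtract. With an IRF calibration (`tau_ref = 0`) this removes the
#' instrument's phase delay and modulation loss. Per-pixel calibrations
#' divide pixel-wise.
#'
#' @param p an [phasor()] or `fli_phasor_image`.
#' @param cal an [phasor_calibration()].
#' @return Same type as `p`, calibrated.
#' @export
calibrate <- function(p, cal) {
  stopifnot(inherits(cal, "fli_calibration"))
  w <- if (inherits(p, "fli_phasor")) phasor_omega(p)
       else 2 * pi * p$harmonic * p$frequency_MHz * 1e-3
  target <- uc_z(cal$reference_lifetime_ns, w)
  if (cal$mode == "single") {
    cz <- phasor_z(cal$phasor)
    if (Mod(cz) < 1e-300) stop("degenerate calibration: zero-modulus phasor")
    if (inherits(p, "fli_phasor")) {
      z <- phasor_z(p) / cz * target
      return(phasor(Re(z), Im(z), p$harmonic, p$frequency_MHz))
    }
    z <- complex(real = p$g, imaginary = p$s) / cz * target
    return(phasor_image_new(matrix(Re(z), nrow(p$g)), matrix(Im(z), nrow(p$g)),
                            p$valid, p$harmonic, p$frequency_MHz))
  }
  # per-pixel
  if (!inherits(p, "fli_phasor_image"))
    stop("per-pixel calibration requires a phasor image")
  cp <- cal$phasor
  if (!all(dim(cp$g) == dim(p$g)))
    stop("per-pixel calibration shape does not match the phasor image")
  cz <- complex(real = cp$g, imaginary = cp$s)
  if (any(Mod(cz[p$valid]) < 1e-300))
    stop("degenerate calibration: zero-modulus phasor at a valid pixel")
  z <- complex(real = p$g, imaginary = p$s) / cz * target
  phasor_image_new(matrix(Re(z), nrow(p$g)), matrix(Im(z), nrow(p$g)),
                   p$valid & is.finite(cp$g), p$harmonic, p$frequency_MHz)
}

uc_z <- function(tau_ns, omega) {
  wt <- omega * tau_ns
  complex(real = 1 / (1 + wt^2), imaginary = wt / (1 + wt^2))
}

#' Universal-circle phasor of a lifetime
#'
#' The locus of single-exponential decays: `g = 1/(1+(wt)^2)`,
#' `s = wt/(1+(wt)^2)` with `wt = omega * tau`. [uc_lifetime()] is its
#' inverse, `tau = s/(g*omega)`, defined for phasors on the circle.
#'
#' @param tau_ns lifetime in ns, >= 0.
#' @param omega angular frequency in 1/ns (see [angular_frequency()]), or
#'   give `axis` + `harmonic`.
#' @param axis optional [time_axis()] from which `omega` is derived.
#' @param harmonic harmonic used with `axis` (default 1).
#' @return An [phasor()] on the universal circle.
#' @export
uc_phasor <- function(tau_ns, omega = NULL, axis = NULL, harmonic = 1L) {
  if (is.null(omega)) omega <- angular_frequency(axis, harmonic)
  if (tau_ns < 0) stop("'tau_ns' must be >= 0")
  z <- uc_z(tau_ns, omega)
  f <- omega / (2 * pi * harmonic) * 1000
  phasor(Re(z), Im(z), harmonic, f)
}

#' @rdname uc_phasor
#' @param p an [phasor()] lying on the universal circle.
#' @param tol maximum allowed distance from the circle (default `1e-6`).
#' @return `uc_lifetime`: the lifetime in ns.
#' @export
uc_lifetime <- function(p, omega = NULL, tol = 1e-6) {
  stopifnot(inherits(p, "fli_phasor"))
  if (is.null(omega)) omega <- phasor_omega(p)
  d <- abs(sqrt((p$g - 0.5)^2 + p$s^2) - 0.5)
  if (d > tol)
    stop(sprintf("phasor is %.3g from the universal circle (tol %.3g)", d, tol))
  if (p$g <= 0) {
    if (abs(p$g) < 1e-15 && abs(p$s) < 1e-15) return(Inf)
    stop("phasor with g <= 0 has no finite UC lifetime")
  }
  p$s / (p$g * omega)
}

#' Phase and modulation lifetimes of a phasor
#'
#' The two standard single-exponential-equivalent lifetimes:
#' `tau_phi = (s/g)/omega` and `tau_m = sqrt(1/(g^2+s^2) - 1)/omega`. They
#' agree with each other (and with [uc_lifetime()]) exactly on the
#' universal circle; strictly inside it `tau_m > tau_phi`, a classic
#' heterogeneity indicator.
#'
#' @param p an [phasor()].
#' @param omega angular frequency (1/ns); default from the phasor itself.
#' @return List with `tau_phase_ns` and `tau_mod_ns` (`NA` with a warning
#'   when the modulus exceeds 1 beyond tolerance).
#' @export
phase_mod_lifetimes <- function(p, omega = NULL) {
  stopifnot(inherits(p, "fli_phasor"))
  if (is.null(omega)) omega <- phasor_omega(p)
  if (p$g <= 0) stop("phase lifetime undefined for g <= 0")
  tau_phi <- (p$s / p$g) / omega
  m2 <- p$g^2 + p$s^2
  if (m2 > 1 + 1e-9) {
    warning("phasor modulus > 1: modulation lifetime unset")
    tau_m <- NA_real_
  } else {
    tau_m <- sqrt(max(1 / m2 - 1, 0)) / omega
  }
  list(tau_phase_ns = tau_phi, tau_mod_ns = tau_m)
}
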