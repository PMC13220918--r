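#' Region of interest in the phasor plot
#'
#' A polygon or disc in `(g, s)` space, used to restrict reference finding
#' to a sub-population or to select the image pixels whose phasors fall in
#' a region.
#'
#' @param vertices n x 2 matrix of polygon vertices (columns g, s), n >= 3;
#'   or `NULL` when giving a disc.
#' @param center,radius disc definition (`radius > 0`).
#' @param name optional label used in reference-finding messages.
#' @return An object of class `fli_phasor_roi`.
#' @export
phasor_roi <- function(vertices = NULL, center = NULL, radius = NULL,
                       name = NULL) {
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2L || nrow(vertices) < 3L)
      stop("polygon needs an n x 2 vertex matrix, n >= 3")
    if (abs(polygon_area(vertices)) < 1e-15)
      stop("degenerate phasor ROI: polygon has zero area")
    structure(list(type = "polygon", vertices = vertices, name = name),
              class = "fli_phasor_roi")
  } else {
    if (is.null(center) || is.null(radius) || radius <= 0)
      stop("disc needs 'center' and positive 'radius'")
    structure(list(type = "disc", center = as.numeric(center),
                   radius = as.numeric(radius), name = name),
              class = "fli_phasor_roi")
  }
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

phasor_roi_contains <- function(region, g, s) {
  if (region$type == "disc") {
    (g - region$center[1])^2 + (s - region$center[2])^2 <= region$radius^2
  } else {
    as.logical(pracma::inpolygon(g, s, region$vertices[, 1],
                                 region$vertices[, 2], boundary = TRUE))
  }
}

#' Select image pixels by phasor-plot region
#'
#' Marks a pixel valid iff its (calibrated) phasor falls inside `region` —
#' the reverse mapping from phasor space back to the image.
#'
#' @param pim an `fli_phasor_image`.
#' @param region an [phasor_roi()].
#' @param combine optional existing logical mask to combine with
#'   (`"and"`/`"or"`).
#' @param mask the mask combined when `combine` is given.
#' @return A logical matrix of class `fli_validity_mask`.
#' @export
phasor_select <- function(pim, region, combine = NULL, mask = NULL) {
  stopifnot(inherits(pim, "fli_phasor_image"),
            inherits(region, "fli_phasor_roi"))
  sel <- matrix(FALSE, nrow(pim$g), ncol(pim$g))
  ok <- which(pim$valid & is.finite(pim$g) & is.finite(pim$s))
  if (length(ok))
    sel[ok] <- phasor_roi_contains(region, pim$g[ok], pim$s[ok])
  if (!is.null(combine)) {
    m <- unclass(mask)
    sel <- switch(match.arg(combine, c("and", "or")),
                  and = sel & m, or = sel | m)
  }
  structure(sel, min_counts = NA_real_, class = "fli_validity_mask")
}

#' Pair of single-exponential phasor references
#'
#' Two phasors on the universal circle with their lifetimes, the basis for
#' two-component linear decomposition. `p1` is the shorter-lifetime
#' (larger-g) reference.
#'
#' @param p1,p2 [phasor()]s on the universal circle.
#' @param tau1_ns,tau2_ns their lifetimes (`tau1 <= tau2`).
#' @param message optional description of how they were obtained.
#' @param degenerate flag set when the pair collapses to a single point
#'   (tangency).
#' @return An object of class `fli_reference_pair`.
#' @export
reference_pair <- function(p1, p2, tau1_ns, tau2_ns, message = NULL,
                           degenerate = FALSE) {
  for (p in list(p1, p2)) {
    d <- abs(sqrt((p$g - 0.5)^2 + p$s^2) - 0.5)
    if (d > 1e-9)
      stop(sprintf("reference phasor is %.3g off the universal circle", d))
  }
  if (tau1_ns > tau2_ns)
    stop("'tau1_ns' must be <= 'tau2_ns' (p1 is the shorter lifetime)")
  structure(list(p1 = p1, p2 = p2, tau1_ns = as.numeric(tau1_ns),
                 tau2_ns = as.numeric(tau2_ns), message = message,
                 degenerate = isTRUE(degenerate)),
            class = "fli_reference_pair")
}

#' @export
print.fli_reference_pair <- function(x, ...) {
  cat(sprintf("<fli_reference_pair> tau1 = %.4g ns, tau2 = %.4g ns%s\n",
              x$tau1_ns, x$tau2_ns,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  invisible(x)
}

collect_phasors <- function(phasors) {
  if (inherits(phasors, "fli_phasor_image")) {
    ok <- which(phasors$valid & is.finite(phasors$g) & is.finite(phasors$s))
    list(g = phasors$g[ok], s = phasors$s[ok], harmonic = phasors$harmonic,
         frequency_MHz = phasors$frequency_MHz)
  } else if (is.list(phasors) &&
             all(vapply(phasors, inherits, logical(1), "fli_phasor"))) {
    list(g = vapply(phasors, `[[`, numeric(1), "g"),
         s = vapply(phasors, `[[`, numeric(1), "s"),
         harmonic = phasors[[1]]$harmonic,
         frequency_MHz = phasors[[1]]$frequency_MHz)
  } else stop("'phasors' must be a phasor image or a list of phasors")
}

#' Universal-circle references from the principal axis of a phasor cloud
#'
#' Finds the two single-exponential references describing a two-component
#' population directly from its phasor scatter: compute the (optionally
#' intensity-weighted) mean and second-moment matrix of the cloud, take the
#' major (or minor) principal axis of inertia, and intersect the line
#' through the mean along that axis with the universal circle (center
#' `(0.5, 0)`, radius `0.5`). A two-component mixture series lies on a
#' chord, so its major axis extended hits the circle at the two component
#' phasors.
#'
#' @param phasors an `fli_phasor_image` or list of [phasor()]s
#'   (calibrated).
#' @param use_major use the major (largest-eigenvalue) axis (default TRUE);
#'   FALSE selects the minor axis.
#' @param selection optional list of [phasor_roi()]s; only phasors inside
#'   at least one region are used.
#' @param weights `"none"` (each phasor counts equally, the default) or a
#'   numeric vector/matrix of weights (e.g. pixel intensities).
#' @param min_axis_ratio degeneracy guard: error when the selected
#'   eigenvalue exceeds the other by less than this ratio (isotropic cloud).
#' @return An [reference_pair()]; `p1` is the larger-g (shorter-lifetime)
#'   intersection. `message` records the selection used. Tangency returns a
#'   degenerate pair with a warning.
#' @export
principal_axis_uc_references <- function(phasors, use_major = TRUE,
                                         selection = NULL, weights = "none",
                                         min_axis_ratio = 1 + 1e-9) {
  ph <- collect_phasors(phasors)
  g <- ph$g; s <- ph$s
  w <- if (identical(weights, "none")) rep(1, length(g))
       else {
         wv <- as.numeric(weights)
         if (inherits(phasors, "fli_phasor_image")) {
           ok <- which(phasors$valid & is.finite(phasors$g) &
                         is.finite(phasors$s))
           wv <- as.numeric(weights)[ok]
         }
         wv
       }
  msg <- "all phasors"
  if (!is.null(selection)) {
    if (inherits(selection, "fli_phasor_roi")) selection <- list(selection)
    inside <- Reduce(`|`, lapply(selection, phasor_roi_contains, g = g, s = s))
    g <- g[inside]; s <- s[inside]; w <- w[inside]
    nms <- vapply(seq_along(selection), function(i) {
      nm <- selection[[i]]$name
      if (is.null(nm)) sprintf("region %d (%s)", i, selection[[i]]$type) else nm
    }, character(1))
    msg <- sprintf("restricted to %d phasor-plot region(s): %s",
                   length(selection), paste(nms, collapse = ", "))
  }
  if (length(unique(complex(real = g, imaginary = s))) < 2L)
    stop("need at least 2 distinct phasors after selection")
  sw <- sum(w)
  mu <- c(sum(w * g), sum(w * s)) / sw
  dg <- g - mu[1]; ds <- s - mu[2]
  M <- matrix(c(sum(w * dg * dg), sum(w * dg * ds),
                sum(w * dg * ds), sum(w * ds * ds)), 2, 2) / sw
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values                      # decreasing
  if (lam[1] <= 0 || lam[1] / max(lam[2], .Machine$double.xmin) <
      min_axis_ratio)
    stop("degenerate axis: phasor cloud is isotropic (eigenvalue ratio ",
         format(lam[1] / max(lam[2], .Machine$double.xmin), digits = 4), ")")
  v <- ev$vectors[, if (use_major) 1 else 2]

  # line mu + t v vs circle |p - (0.5, 0)| = 0.5
  mc <- mu - c(0.5, 0)
  b <- sum(v * mc)
  cc <- sum(mc * mc) - 0.25
  disc <- b^2 - cc
  if (disc < 0)
    stop("principal axis does not intersect the universal circle")
  f <- ph$frequency_MHz
  omega <- 2 * pi * ph$harmonic * f * 1e-3
  mk <- function(t) {
    p <- mu + t * v
    # snap exactly onto the circle (guards uc_lifetime's tolerance)
    ang <- atan2(p[2], p[1] - 0.5)
    phasor(0.5 + 0.5 * cos(ang), 0.5 * sin(ang), ph$harmonic, f)
  }
  if (disc < 1e-24) {
    warning("principal axis is tangent to the universal circle: ",
            "degenerate reference pair")
    p0 <- mk(-b)
    tau <- uc_lifetime(p0, omega)
    return(reference_pair(p0, p0, tau, tau, message = msg, degenerate = TRUE))
  }
  r <- sqrt(disc)
  pa <- mk(-b - r)
  pb <- mk(-b + r)
  if (pa$g < pb$g) { tmp <- pa; pa <- pb; pb <- tmp }   # p1 = larger g
  reference_pair(pa, pb, uc_lifetime(pa, omega), uc_lifetime(pb, omega),
                 message = msg)
}

#' Two-component linear decomposition of a phasor
#'
#' Orthogonal projection of a phasor onto the segment joining the two
#' references: `f1` is the intensity fraction of reference 1, obtained as
#' `((p - p2) . (p1 - p2)) / |p1 - p2|^2`, clamped to `[0, 1]` (with a
#' flag) rather than extrapolated. The perpendicular distance to the
#' segment is reported as the residual; decompositions beyond
#' `max_residual` are marked invalid so maps and histograms can exclude
#' them.
#'
#' @param p an [phasor()] (calibrated).
#' @param refs an [reference_pair()].
#' @param max_residual optional residual bound in phasor units.
#' @return An object of class `fli_decomposition` with fields `f1`, `f2`
#'   (`f1 + f2 = 1`), `residual`, `clamped`, `valid`.
#' @export
decompose_phasor <- function(p, refs, max_residual = NULL) {
  stopifnot(inherits(p, "fli_phasor"), inherits(refs, "fli_reference_pair"))
  d1 <- c(refs$p1$g - refs$p2$g, refs$p1$s - refs$p2$s)
  len2 <- sum(d1^2)
  if (len2 < 1e-20) stop("degenerate reference pair: coincident references")
  dp <- c(p$g - refs$p2$g, p$s - refs$p2$s)
  f1_raw <- sum(dp * d1) / len2
  clamped <- f1_raw < 0 || f1_raw > 1
  f1 <- min(max(f1_raw, 0), 1)
  residual <- abs(dp[1] * d1[2] - dp[2] * d1[1]) / sqrt(len2)
  valid <- is.null(max_residual) || residual <= max_residual
  structure(list(f1 = f1, f2 = 1 - f1, f1_raw = f1_raw,
                 residual = residual, clamped = clamped, valid = valid),
            class = "fli_decomposition")
}

#' @export
print.fli_decomposition <- function(x, ...) {
  cat(sprintf(
    "<fli_decomposition> f1 = %.4g, f2 = %.4g, residual = %.3g%s%s\n",
    x$f1, x$f2, x$residual,
    if (x$clamped) " [clamped]" else "",
    if (!x$valid) " [invalid]" else ""))
  invisible(x)
}

#' Amplitude-averaged lifetime from a decomposition
#'
#' Phasor fractions weight components by emitted intensity (`a_i tau_i`);
#' converting to pre-exponential amplitude fractions (`a_i ~ f_i / tau_i`)
#' gives the amplitude-averaged lifetime
#' `<tau>_a = sum(a_i tau_i) / sum(a_i) = 1 / (f1/tau1 + f2/tau2)`,
#' which always lies in `[tau1, tau2]`.
#'
#' @param dec an [decompose_phasor()] result (or a plain `f1` in `[0, 1]`).
#' @param refs an [reference_pair()] with positive lifetimes.
#' @return `<tau>_a` in ns.
#' @export
amplitude_avg_lifetime <- function(dec, refs) {
  f1 <- if (inherits(dec, "fli_decomposition")) dec$f1 else as.numeric(dec)
  if (inherits(dec, "fli_decomposition") && !dec$valid)
    stop("decomposition marked invalid (residual beyond bound)")
  if (f1 < 0 || f1 > 1) stop("'f1' must lie in [0, 1]")
  t1 <- refs$tau1_ns; t2 <- refs$tau2_ns
  if (t1 <= 0 || t2 <= 0) stop("reference lifetimes must be positive")
  1 / (f1 / t1 + (1 - f1) / t2)
}
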