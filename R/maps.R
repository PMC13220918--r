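#' Parameter map
#'
#' A `(row, col)` matrix of an analysis output (lifetime, fraction,
#' chi-square, ...) with an explicit unset state (`NA`), a name and units.
#'
#' @param values numeric matrix; `NA` marks unset pixels.
#' @param name quantity name.
#' @param units units string (e.g. `"ns"`).
#' @param provenance free-form note on which analysis produced it.
#' @return A matrix of class `fli_map`.
#' @export
parameter_map <- function(values, name = "value", units = "",
                          provenance = NULL) {
  stopifnot(is.matrix(values))
  if (any(is.infinite(values), na.rm = TRUE))
    stop("map values must be finite wherever set")
  structure(values, name = name, units = units, provenance = provenance,
            class = c("fli_map", "matrix"))
}

#' @export
print.fli_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<fli_map> '%s'%s, %d x %d, %d set, range [%.4g, %.4g]\n",
              attr(x, "name"),
              if (nzchar(attr(x, "units"))) paste0(" (", attr(x, "units"), ")")
              else "",
              nrow(v), ncol(v), sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Fill a map from per-ROI values
#'
#' Paints each ROI's pixels with its value; background stays unset. When
#' ROIs overlap the last-listed ROI wins and the overlap is flagged in
#' attribute `"overlap"` (a logical matrix).
#'
#' @param rs an [roi_set()].
#' @param values named numeric vector, names = ROI ids (every id present).
#' @param name,units passed to [parameter_map()].
#' @return An `fli_map`.
#' @export
map_from_rois <- function(rs, values, name = "value", units = "") {
  stopifnot(inherits(rs, "fli_roi_set"))
  ids <- roi_ids(rs)
  missing <- setdiff(as.character(ids), names(values))
  if (length(missing))
    stop("no value for ROI id(s): ", paste(missing, collapse = ", "))
  m <- matrix(NA_real_, rs$shape[1], rs$shape[2])
  seen <- matrix(FALSE, rs$shape[1], rs$shape[2])
  overlap <- matrix(FALSE, rs$shape[1], rs$shape[2])
  for (r in rs$rois) {
    idx <- r$pixels[, 1] + 1L + rs$shape[1] * r$pixels[, 2]
    overlap[idx[seen[idx]]] <- TRUE
    m[idx] <- as.numeric(values[[as.character(r$id)]])
    seen[idx] <- TRUE
  }
  out <- parameter_map(m, name = name, units = units,
                       provenance = "map_from_rois")
  attr(out, "overlap") <- overlap
  out
}

#' Histogram of a parameter map
#'
#' Histogram over set values only; total counts equal the number of set
#' pixels for any binning.
#'
#' @param m an `fli_map` (or numeric matrix/vector; `NA` = unset).
#' @param bins a bin count or an explicit vector of break edges.
#' @return List with `edges` (length nbins+1), `mids` and `counts`.
#' @export
histogram_map <- function(m, bins = 32) {
  v <- as.numeric(unclass(m))
  v <- v[!is.na(v)]
  if (!length(v)) stop("no set values to histogram")
  if (length(bins) == 1L) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else edges <- as.numeric(bins)
  h <- graphics::hist(v, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(edges = h$breaks, mids = h$mids, counts = h$counts)
}

#' Multi-peak Gaussian fit of a histogram
#'
#' Least-squares fit of a sum of Gaussians (area parameterization:
#' `count(x) = sum_j area_j * dnorm(x, mean_j, sigma_j) * binwidth`) to the
#' histogram's bin centers and counts. Initialization is deterministic from
#' the `n_peaks` tallest local maxima. Peaks are reported sorted by mean.
#'
#' @param hist a [histogram_map()] result (list with `edges`/`mids`/
#'   `counts`).
#' @param n_peaks number of Gaussian components (>= 1).
#' @param init optional data frame with columns `mean`, `sigma`, `area`.
#' @return An object of class `fli_peak_fit`: data frame `peaks`
#'   (mean/sigma/area), `chi2_reduced`, `converged`, `fitted` (per bin).
#' @export
fit_peaks <- function(hist, n_peaks = 1L, init = NULL) {
  x <- hist$mids
  y <- as.numeric(hist$counts)
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L) stop("'n_peaks' must be >= 1")
  nonzero <- sum(y > 0)
  if (nonzero <= 3L * n_peaks)
    stop("too few non-empty bins (", nonzero, ") for ", n_peaks, " peak(s)")
  bw <- mean(diff(hist$edges))

  if (is.null(init)) {
    is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) & y > 0
    cand <- order(-y * is_max)[seq_len(min(sum(is_max), n_peaks))]
    if (length(cand) < n_peaks)
      cand <- unique(c(cand, order(-y)))[seq_len(n_peaks)]
    # crude width: second moment of the whole histogram, split across peaks
    mu_all <- sum(x * y) / sum(y)
    sd_all <- sqrt(sum(y * (x - mu_all)^2) / sum(y))
    if (!is.finite(sd_all) || sd_all <= 0)
      stop("degenerate histogram width: all mass in one bin")
    init <- data.frame(mean = x[cand],
                       sigma = rep(max(sd_all / n_peaks, bw / 2), n_peaks),
                       area = y[cand] * sqrt(2 * pi) *
                         max(sd_all / n_peaks, bw / 2) / bw)
  }
  if (any(init$sigma <= 0) || any(init$area <= 0))
    stop("degenerate peak initialization (non-positive sigma or area)")

  p0 <- c(rbind(init$mean, log(init$sigma), log(init$area)))
  model <- function(p) {
    out <- numeric(length(x))
    for (j in seq_len(n_peaks)) {
      mu <- p[3 * j - 2]; sg <- exp(p[3 * j - 1]); ar <- exp(p[3 * j])
      out <- out + ar * stats::dnorm(x, mu, sg) * bw
    }
    out
  }
  rng <- range(hist$edges)
  # a histogram cannot resolve structure below its bin width
  lower <- rep(c(rng[1], log(bw / 2), log(1e-9)), n_peaks)
  upper <- rep(c(rng[2], log(diff(rng)), log(sum(y) * 1e3 + 1)), n_peaks)
  lm <- minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p),
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-14, ptol = 1e-14, maxiter = 500))
  p <- lm$par
  peaks <- data.frame(mean = p[3 * seq_len(n_peaks) - 2],
                      sigma = exp(p[3 * seq_len(n_peaks) - 1]),
                      area = exp(p[3 * seq_len(n_peaks)]))
  peaks <- peaks[order(peaks$mean), , drop = FALSE]
  rownames(peaks) <- NULL
  dof <- max(length(y) - 3L * n_peaks, 1L)
  chi2 <- sum((y - model(p))^2 / pmax(y, 1)) / dof
  structure(list(peaks = peaks, n_peaks = n_peaks, chi2_reduced = chi2,
                 converged = lm$info %in% 1:4, fitted = model(p)),
            class = "fli_peak_fit")
}

#' @export
print.fli_peak_fit <- function(x, ...) {
  cat(sprintf("<fli_peak_fit> %d peak(s), chi2_red = %.4g%s\n", x$n_peaks,
              x$chi2_reduced, if (!x$converged) " [not converged]" else ""))
  print(x$peaks)
  invisible(x)
}

#' Scatter table of two parameter maps
#'
#' One row per pixel where both maps are set — the data behind a
#' parameter-vs-parameter scatter plot (e.g. lifetime vs intensity).
#'
#' @param x,y `fli_map`s (or matrices) of the same shape.
#' @param names column names for the two values.
#' @return Data frame with columns `pixel` (linear index), `row`, `col`
#'   (0-based) and the two values.
#' @export
scatter_table <- function(x, y, names = c("x", "y")) {
  xm <- unclass(x); ym <- unclass(y)
  if (!all(dim(xm) == dim(ym))) stop("maps have different shapes")
  ok <- which(!is.na(xm) & !is.na(ym))
  rc <- arrayInd(ok, dim(xm))
  out <- data.frame(pixel = ok, row = rc[, 1] - 1L, col = rc[, 2] - 1L,
                    xm[ok], ym[ok])
  names(out)[4:5] <- names
  out
}

#' Transform a map through a calibration curve
#'
#' Piecewise-linear interpolation of each set value through a measured
#' `(x, y)` curve — e.g. converting a lifetime map to membrane potential
#' via an experimental `V(tau)` calibration. Out-of-range values become
#' unset; their count is attached as attribute `"n_out_of_range"`.
#'
#' @param m an `fli_map` (or matrix).
#' @param curve data frame / matrix of `(x, y)` pairs, `x` strictly
#'   monotone, >= 2 rows.
#' @param monotone additionally require `y` monotone (error otherwise).
#' @param name,units metadata of the output map.
#' @return An `fli_map`.
#' @export
map_through_curve <- function(m, curve, monotone = FALSE,
                              name = "converted", units = "") {
  if (is.data.frame(curve)) {
    cx <- as.numeric(curve[[1]]); cy <- as.numeric(curve[[2]])
  } else {
    curve <- as.matrix(curve)
    cx <- as.numeric(curve[, 1]); cy <- as.numeric(curve[, 2])
  }
  if (length(cx) < 2L) stop("curve needs at least 2 points")
  dx <- diff(cx)
  if (!(all(dx > 0) || all(dx < 0))) stop("curve x must be strictly monotone")
  if (monotone) {
    dy <- diff(cy)
    if (!(all(dy >= 0) || all(dy <= 0)))
      stop("curve y is not monotone (monotone = TRUE)")
  }
  if (dx[1] < 0) { cx <- rev(cx); cy <- rev(cy) }
  v <- unclass(m)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- which(!is.na(v))
  if (length(ok))
    out[ok] <- stats::approx(cx, cy, xout = v[ok], rule = 1)$y
  n_oor <- sum(!is.na(v)) - sum(!is.na(out))
  res <- parameter_map(out, name = name, units = units,
                       provenance = "map_through_curve")
  attr(res, "n_out_of_range") <- n_oor
  res
}

#' Export a map as a CSV matrix
#'
#' Writes the raw value matrix; unset pixels become empty fields (the
#' portable representation — NaN dialects vary across readers).
#'
#' @param m an `fli_map` (or matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_map_csv <- function(m, path) {
  v <- unclass(m)
  txt <- matrix(ifelse(is.na(v), "", formatC(v, digits = 15, format = "g")),
                nrow(v), ncol(v))
  utils::write.table(txt, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV matrix written by [export_map_csv()]
#'
#' @param path CSV path.
#' @return Numeric matrix with `NA` for empty fields.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, header = FALSE,
                        colClasses = "character")
  m <- apply(as.matrix(df), c(1, 2), function(z)
    if (!nzchar(trimws(z))) NA_real_ else as.numeric(z))
  unname(m)
}

#' Render a map to RGB through a linear color ramp
#'
#' The documented stand-in for on-screen color overlays: values are mapped
#' linearly between `range` endpoints through a color ramp; unset pixels
#' get `na_color`.
#'
#' @param m an `fli_map`.
#' @param range value range mapped to the ramp ends (default: data range).
#' @param colors ramp endpoint colors.
#' @param na_color color for unset pixels.
#' @return Character matrix of hex colors.
#' @export
map_to_rgb <- function(m, range = NULL, colors = c("#000080", "#FFFF00"),
                       na_color = "#000000") {
  v <- unclass(m)
  if (is.null(range)) range <- base::range(v, na.rm = TRUE)
  ramp <- grDevices::colorRamp(colors)
  z <- pmin(pmax((v - range[1]) / diff(range), 0), 1)
  out <- matrix(na_color, nrow(v), ncol(v))
  ok <- which(!is.na(z))
  rgbm <- ramp(z[ok])
  out[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                            maxColorValue = 255)
  out
}
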