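#' Spatial binning of an image cube
#'
#' Sums non-overlapping `k x k` pixel blocks in every time frame, trading
#' spatial resolution for photon counts (the usual remedy for noisy
#' per-pixel decays). Trailing partial rows/columns are dropped so every
#' output pixel aggregates exactly `k^2` inputs.
#'
#' @param ds an [fli_dataset()].
#' @param k block side (positive integer); `k = 1` is the identity.
#' @return A binned [fli_dataset()] with dims `floor(dim/k)`.
#' @export
bin_spatial <- function(ds, k) {
  stopifnot(inherits(ds, "fli_dataset"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a positive integer")
  if (k == 1L) return(ds)
  d <- dim(ds$counts)
  nr <- d[2] %/% k
  nc <- d[3] %/% k
  if (nr < 1L || nc < 1L) stop("block size exceeds image dimensions")
  cube <- ds$counts[, seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  # sum k-blocks along rows then cols via dimension folding
  dim(cube) <- c(d[1], k, nr, nc * k)
  cube <- colSums(aperm(cube, c(2, 1, 3, 4)))
  dim(cube) <- c(d[1], nr, k, nc)
  cube <- colSums(aperm(cube, c(3, 1, 2, 4)))
  meta <- ds$meta
  meta$bin_spatial <- k
  fli_dataset(array(cube, c(d[1], nr, nc)), ds$time_axis, meta)
}

#' Temporal binning of an image cube
#'
#' Sums groups of `k` consecutive time bins. New bin centers are the plain
#' means of the merged centers. If `k` does not divide the bin count the
#' trailing bins are dropped (recorded in `meta$dropped_time_bins`).
#'
#' @param ds an [fli_dataset()].
#' @param k group size (positive integer); `k = 1` is the identity.
#' @return An [fli_dataset()] with `floor(n_bins/k)` time bins.
#' @export
bin_temporal <- function(ds, k) {
  stopifnot(inherits(ds, "fli_dataset"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a positive integer")
  if (k == 1L) return(ds)
  d <- dim(ds$counts)
  nt <- d[1] %/% k
  if (nt < 1L) stop("'k' exceeds the number of time bins")
  keep <- nt * k
  cube <- ds$counts[seq_len(keep), , , drop = FALSE]
  dim(cube) <- c(k, nt, d[2], d[3])
  cube <- colSums(cube)
  centers <- colMeans(matrix(ds$time_axis$bin_centers_ns[seq_len(keep)],
                             nrow = k))
  ax <- time_axis(nt, period_ns = ds$time_axis$period_ns,
                  bin_centers_ns = centers)
  meta <- ds$meta
  meta$bin_temporal <- k
  if (keep < d[1]) meta$dropped_time_bins <- d[1] - keep
  fli_dataset(array(cube, c(nt, d[2], d[3])), ax, meta)
}

#' Background subtraction
#'
#' Removes a constant background per bin, either given (`mode = "constant"`)
#' or estimated per pixel as the mean count over a pre-pulse window of time
#' bins (`mode = "from_bins"`). Results are clamped at zero to keep the
#' count cube non-negative. The estimated per-pixel background is attached
#' as attribute `"background"`.
#'
#' @param ds an [fli_dataset()].
#' @param mode `"constant"` or `"from_bins"`.
#' @param c background counts per bin (constant mode), >= 0.
#' @param window integer vector of time-bin indices forming a
#'   pure-background region (from_bins mode).
#' @return A corrected [fli_dataset()]; `attr(, "background")` holds the
#'   per-pixel background estimate (matrix), or the scalar used.
#' @export
subtract_background <- function(ds, mode = c("constant", "from_bins"),
                                c = 0, window = NULL) {
  stopifnot(inherits(ds, "fli_dataset"))
  mode <- match.arg(mode)
  d <- dim(ds$counts)
  if (mode == "constant") {
    if (!is.finite(c) || c < 0) stop("'c' must be >= 0")
    bg <- c
    cube <- pmax(ds$counts - c, 0)
  } else {
    if (is.null(window) || length(window) == 0L)
      stop("'window' must name at least one time bin")
    window <- as.integer(window)
    if (any(window < 1L) || any(window > d[1]))
      stop("'window' indices out of range")
    bg <- apply(ds$counts[window, , , drop = FALSE], c(2, 3), mean)
    cube <- pmax(sweep(ds$counts, c(2, 3), bg, "-"), 0)
  }
  out <- fli_dataset(array(cube, d), ds$time_axis, ds$meta)
  attr(out, "background") <- bg
  out
}

#' Pile-up correction for gated single-photon acquisitions
#'
#' With `n_frames` exposures per bin and at most one detected photon per
#' frame, the recorded count `n` saturates as `n = N (1 - exp(-m/N))` where
#' `m` is the true (linear) count and `N = n_frames`. This inverts that map:
#' `m = -N log(1 - n/N)`. The corrected cube is real-valued, >= the input,
#' and approaches it as `n/N -> 0`.
#'
#' @param ds an [fli_dataset()].
#' @param n_frames number of exposures per time bin (positive integer);
#'   every count must be strictly below it.
#' @return A corrected, real-valued [fli_dataset()].
#' @export
correct_pileup <- function(ds, n_frames) {
  stopifnot(inherits(ds, "fli_dataset"))
  if (!is.finite(n_frames) || n_frames < 1)
    stop("'n_frames' must be a positive number")
  sat <- which(ds$counts >= n_frames)
  if (length(sat)) {
    idx <- arrayInd(sat[1], dim(ds$counts))
    stop(sprintf(
      "saturated count at time bin %d, pixel (%d, %d): %g >= n_frames = %g",
      idx[1], idx[2], idx[3], ds$counts[sat[1]], n_frames))
  }
  cube <- -n_frames * log1p(-ds$counts / n_frames)
  meta <- ds$meta
  meta$pileup_n_frames <- n_frames
  fli_dataset(array(cube, dim(ds$counts)), ds$time_axis, meta)
}

#' Pixel validity mask from an intensity threshold
#'
#' Flags pixels whose total photon count reaches `min_counts`; downstream
#' per-pixel analyses (phasor images, pixel-wise fits) skip invalid pixels.
#'
#' @param ds an [fli_dataset()].
#' @param min_counts threshold on the per-pixel total (>= 0).
#' @return Logical matrix of class `fli_validity_mask` with attribute
#'   `min_counts`.
#' @export
validity_mask <- function(ds, min_counts = 0) {
  stopifnot(inherits(ds, "fli_dataset"))
  if (!is.finite(min_counts) || min_counts < 0)
    stop("'min_counts' must be >= 0")
  v <- intensity_image(ds) >= min_counts
  structure(v, min_counts = min_counts, class = "fli_validity_mask")
}
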