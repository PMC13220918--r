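#' Time-resolved fluorescence image cube
#'
#' The central container: a 3-D array of photon counts indexed
#' `(time_bin, row, col)` together with its [time_axis()] and free-form
#' metadata. Counts are non-negative; they may be non-integer after
#' corrections such as pile-up inversion.
#'
#' @param counts 3-D numeric array `(time, row, col)`, all values >= 0.
#' @param time_axis an [time_axis()] whose `n_bins` matches `dim(counts)[1]`.
#' @param meta named list of provenance key/value pairs (values coerced to
#'   character on HDF5 export).
#' @return An object of class `fli_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [simulate_scene()]
#' @export
fli_dataset <- function(counts, time_axis, meta = list()) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be a 3-D array (time, row, col)")
  if (!inherits(time_axis, "fli_time_axis"))
    stop("'time_axis' must be a fli_time_axis")
  if (dim(counts)[1] != time_axis$n_bins)
    stop(sprintf("counts has %d time bins but time_axis has %d",
                 dim(counts)[1], time_axis$n_bins))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  structure(list(counts = counts, time_axis = time_axis, meta = meta),
            class = "fli_dataset")
}

#' @export
print.fli_dataset <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<fli_dataset> %d x %d pixels, %d time bins, period %.6g ns, %.4g counts\n",
    d[2], d[3], d[1], x$time_axis$period_ns, sum(x$counts)))
  invisible(x)
}

#' @export
dim.fli_dataset <- function(x) dim(x$counts)

#' Intensity image of a dataset
#'
#' Per-pixel total photon count (sum over time bins) — what a camera would
#' record with gating off.
#'
#' @param ds an [fli_dataset()].
#' @return Numeric matrix `(row, col)`.
#' @export
intensity_image <- function(ds) {
  stopifnot(inherits(ds, "fli_dataset"))
  apply(ds$counts, c(2, 3), sum)
}

#' Fluorescence decay curve
#'
#' A single decay: counts per time bin with their bin-center times.
#'
#' @param time_ns numeric vector of bin centers (ns).
#' @param counts non-negative numeric vector, same length.
#' @return An object of class `fli_decay`.
#' @export
decay_curve <- function(time_ns, counts) {
  time_ns <- as.numeric(time_ns)
  counts <- as.numeric(counts)
  if (length(time_ns) != length(counts))
    stop("'time_ns' and 'counts' must have equal length")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  structure(list(time_ns = time_ns, counts = counts), class = "fli_decay")
}

#' @export
print.fli_decay <- function(x, ...) {
  cat(sprintf("<fli_decay> %d bins, %.4g counts\n",
              length(x$counts), sum(x$counts)))
  invisible(x)
}
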