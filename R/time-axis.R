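#' Time axis of a time-resolved acquisition
#'
#' Describes the temporal sampling of a fluorescence decay: the laser period
#' `T` (ns), the number of time bins, and the bin centers within `[0, T)`.
#' The phasor (repetition) frequency is `f = 1/T`, reported in MHz, and the
#' angular frequency at harmonic `n` is `omega = 2*pi*n/T` (1/ns).
#'
#' @param n_bins number of time bins (positive integer).
#' @param period_ns laser period `T` in ns. Give either `period_ns` or
#'   `frequency_MHz`.
#' @param frequency_MHz laser repetition frequency in MHz (`1000/period_ns`).
#' @param bin_centers_ns optional explicit bin centers in ns, strictly
#'   increasing, all in `[0, period_ns)`. Default: a uniform grid with the
#'   first center at half a bin width.
#' @return An object of class `fli_time_axis` with fields `n_bins`,
#'   `period_ns`, `frequency_MHz` and `bin_centers_ns`.
#' @examples
#' ax <- time_axis(256, frequency_MHz = 78.02)
#' ax$period_ns
#' @export
time_axis <- function(n_bins, period_ns = NULL, frequency_MHz = NULL,
                      bin_centers_ns = NULL) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1L)
    stop("'n_bins' must be a single positive integer")
  if (is.null(period_ns) && is.null(frequency_MHz))
    stop("give either 'period_ns' or 'frequency_MHz'")
  if (is.null(period_ns)) period_ns <- 1000 / frequency_MHz
  if (!is.finite(period_ns) || period_ns <= 0)
    stop("'period_ns' must be positive and finite")
  frequency_MHz <- 1000 / period_ns
  if (is.null(bin_centers_ns)) {
    dt <- period_ns / n_bins
    bin_centers_ns <- (seq_len(n_bins) - 0.5) * dt
  }
  bin_centers_ns <- as.numeric(bin_centers_ns)
  if (length(bin_centers_ns) != n_bins)
    stop("'bin_centers_ns' must have length 'n_bins'")
  if (any(diff(bin_centers_ns) <= 0))
    stop("'bin_centers_ns' must be strictly increasing")
  if (any(bin_centers_ns < 0) || any(bin_centers_ns >= period_ns))
    stop("'bin_centers_ns' must lie in [0, period_ns)")
  structure(
    list(n_bins = n_bins, period_ns = period_ns,
         frequency_MHz = frequency_MHz, bin_centers_ns = bin_centers_ns),
    class = "fli_time_axis")
}

#' Angular frequency of a time axis at a harmonic
#'
#' @param axis an [time_axis()] object.
#' @param harmonic positive integer harmonic `n`.
#' @return `2*pi*n/T` in 1/ns.
#' @export
angular_frequency <- function(axis, harmonic = 1L) {
  stopifnot(inherits(axis, "fli_time_axis"), harmonic >= 1)
  2 * pi * harmonic / axis$period_ns
}

#' @export
print.fli_time_axis <- function(x, ...) {
  cat(sprintf("<fli_time_axis> %d bins, period %.6g ns (f = %.6g MHz)\n",
              x$n_bins, x$period_ns, x$frequency_MHz))
  invisible(x)
}

# uniform-grid check used by operations that need an equispaced axis
is_uniform_axis <- function(axis, tol = 1e-9) {
  d <- diff(axis$bin_centers_ns)
  length(d) == 0L || (max(d) - min(d)) <= tol * mean(d)
}
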