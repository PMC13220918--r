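# Shared fixtures and independent oracles used across test files.

ax_default <- function(n_bins = 256) time_axis(n_bins, frequency_MHz = 78.02)

gauss_irf <- function(axis, center = 1.0, fwhm = 0.4) {
  make_irf(axis, center, fwhm)
}

# brute-force k x k block-sum oracle (loops, no vectorized folding)
oracle_bin_spatial <- function(cube, k) {
  d <- dim(cube)
  nr <- d[2] %/% k; nc <- d[3] %/% k
  out <- array(0, c(d[1], nr, nc))
  for (t in seq_len(d[1]))
    for (i in seq_len(nr))
      for (j in seq_len(nc))
        out[t, i, j] <- sum(cube[t, ((i - 1) * k + 1):(i * k),
                                 ((j - 1) * k + 1):(j * k)])
  out
}

oracle_bin_temporal <- function(cube, k) {
  d <- dim(cube)
  nt <- d[1] %/% k
  out <- array(0, c(nt, d[2], d[3]))
  for (t in seq_len(nt))
    out[t, , ] <- apply(cube[((t - 1) * k + 1):(t * k), , , drop = FALSE],
                        c(2, 3), sum)
  out
}

# BFS flood fill, independent of the igraph-based implementation
oracle_components <- function(fg, connectivity = 8) {
  d <- dim(fg)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (start in seq_along(fg)) {
    if (!fg[start] || lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% d[1] + 1L
      pc <- (p - 1L) %/% d[1] + 1L
      for (o in seq_len(nrow(offs))) {
        rr <- pr + offs[o, 1]; cc <- pc + offs[o, 2]
        if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2]) {
          q <- rr + d[1] * (cc - 1L)
          if (fg[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# O(n^2) direct-sum circular reconvolution oracle: wrapped exponential on
# the lag grid (half-weight at the wrap discontinuity) convolved with the
# unit-normalized IRF by explicit looping.
oracle_model_decay <- function(amplitudes, lifetimes_ns, background,
                               irf_counts, n, T) {
  dt <- T / n
  f <- numeric(n)
  for (i in seq_along(amplitudes)) {
    tau <- lifetimes_ns[i]
    q <- exp(-T / tau)
    v <- amplitudes[i] * exp(-(0:(n - 1)) * dt / tau) / (1 - q)
    v[1] <- amplitudes[i] * (1 + q) / (2 * (1 - q))
    f <- f + v
  }
  h <- irf_counts / sum(irf_counts)
  out <- numeric(n)
  for (k in seq_len(n))
    for (j in seq_len(n))
      out[k] <- out[k] + h[j] * f[((k - j) %% n) + 1]
  out + background
}

phasor_dist <- function(a, b) sqrt((a$g - b$g)^2 + (a$s - b$s)^2)

# uniform small random count cube
random_cube <- function(nt, nr, nc, lambda = 5, seed = 11) {
  set.seed(seed)
  array(rpois(nt * nr * nc, lambda), c(nt, nr, nc))
}
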