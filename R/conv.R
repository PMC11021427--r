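# FFT-based 2-D linear convolution, "same" cropping. Kernels are odd-sized
# and centred; all kernels used in the package are symmetric, so convolution
# and correlation coincide.
conv2_same <- function(a, k) {
  nr <- nrow(a); nc <- ncol(a)
  kr <- nrow(k); kc <- ncol(k)
  ri <- (kr - 1L) %/% 2L; rj <- (kc - 1L) %/% 2L
  pr <- stats::nextn(nr + kr - 1L)
  pc <- stats::nextn(nc + kc - 1L)
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- a
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  f <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  f[(ri + 1L):(ri + nr), (rj + 1L):(rj + nc)]
}

# Gaussian smoothing with edge renormalisation (divides by the kernel mass
# actually inside the grid, so edges are not darkened).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  g1 <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- outer(g1, g1)
  k <- k / sum(k)
  num <- conv2_same(m, k)
  den <- conv2_same(matrix(1, nrow(m), ncol(m)), k)
  num / den
}

# distance-decay kernel for one threat, in cell units, cropped to the grid
# extent (no pair of in-grid cells is farther apart than the grid diagonal)
decay_kernel <- function(max_dist_m, decay, cell_size, n_rows, n_cols) {
  r_cells <- floor(max_dist_m / cell_size)
  r_cells <- min(r_cells, max(n_rows, n_cols) - 1L)
  off <- seq(-r_cells, r_cells)
  d <- cell_size * sqrt(outer(off^2, off^2, "+"))
  matrix(decay_factor(as.vector(d), max_dist_m / 1000, decay),
         nrow(d), ncol(d))
}
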