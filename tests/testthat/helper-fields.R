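# Shared fixtures: seeded band-limited fields, velocity fields, inner
# products, and a brute-force DFT differentiation oracle kept independent
# of the package's FFT path.

grid_axis <- function(g, a = 1) {
  (seq_len(gridDims(g)[a]) - 1) * gridSpacing(g)[a]
}

# Seeded real 2D field with spectrum confined to |k_a| <= kmax, scaled to
# max |f| = mag. Smooth by construction.
bandlimited_values <- function(n, seed, kmax = 3, mag = 1) {
  set.seed(seed)
  x <- (seq_len(n) - 1) * 2 * pi / n
  f <- matrix(0, n, n)
  for (k1 in 0:kmax) {
    for (k2 in -kmax:kmax) {
      if (k1 == 0 && k2 <= 0) next
      f <- f + stats::rnorm(1) / (1 + k1^2 + k2^2) *
        cos(outer(k1 * x, rep(1, n)) + outer(rep(1, n), k2 * x) +
            stats::runif(1, 0, 2 * pi))
    }
  }
  f * mag / max(abs(f))
}

bandlimited_field <- function(g, seed, kmax = 3, mag = 1) {
  scalarField(g, bandlimited_values(gridDims(g)[1], seed, kmax, mag))
}

rand_velocity <- function(g, seed, kmax = 2, mag = 0.3) {
  n <- gridDims(g)[1]
  velocityField(g, list(bandlimited_values(n, seed, kmax, mag),
                        bandlimited_values(n, seed + 1000, kmax, mag)))
}

vf_inner <- function(u, w) {
  g <- gridOf(u)
  hd <- prod(gridSpacing(g))
  s <- 0
  for (a in seq_along(gridDims(g))) {
    s <- s + sum(fieldValues(velocityComponent(u, a)) *
                 fieldValues(velocityComponent(w, a)))
  }
  hd * s
}

vf_norm <- function(u) sqrt(vf_inner(u, u))

vf_lincomb <- function(a, u, b, w) {
  g <- gridOf(u)
  velocityField(g, lapply(seq_along(gridDims(g)), function(i) {
    a * fieldValues(velocityComponent(u, i)) +
      b * fieldValues(velocityComponent(w, i))
  }))
}

vf_maxabs_diff <- function(u, w) {
  max(vapply(seq_along(gridDims(gridOf(u))), function(a) {
    max(abs(fieldValues(velocityComponent(u, a)) -
            fieldValues(velocityComponent(w, a))))
  }, numeric(1)))
}

# Brute-force 1D DFT differentiation matrix by direct O(n^2) summation:
# f'(x_j) = (1/n) sum_m f(x_m) sum_k ik e^{ik(x_j - x_m)}, Nyquist zeroed.
# Independent of stats::fft.
dft_deriv_matrix <- function(n) {
  h <- 2 * pi / n
  ks <- c(0:(n / 2 - 1), 0, if (n > 2) -((n / 2 - 1):1) else NULL)
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (m in seq_len(n)) {
      D[j, m] <- Re(sum(1i * ks * exp(1i * ks * (j - m) * h))) / n
    }
  }
  D
}

# Apply the DFT-summation derivative along one axis of a 2D array.
dft_gradient_oracle <- function(vals, axis) {
  D <- dft_deriv_matrix(dim(vals)[axis])
  if (axis == 1) D %*% vals else vals %*% t(D)
}
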