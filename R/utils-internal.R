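# Internal numerical helpers shared across modules. None exported.

# d-dimensional forward / inverse FFT. R's stats::fft handles arrays of any
# rank; the inverse is unnormalized, so divide by the number of samples.
fftn <- function(x) stats::fft(x)

ifftn <- function(X) {
  out <- stats::fft(X, inverse = TRUE) / length(X)
  out
}

# Inverse FFT of a spectrum known to come from a real field: discard the
# imaginary rounding residue.
ifftn_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# Replicate a per-axis vector (length dims[axis]) along the other axes.
axis_array <- function(vec, dims, axis) {
  array(vec[slice.index(array(0L, dims), axis)], dim = dims)
}

# Signed integer wavenumbers for an even-length axis, Nyquist mode zeroed --
# the standard convention for odd-order (first) spectral derivatives.
deriv_wavenumbers <- function(n) {
  stopifnot(n %% 2L == 0L)
  c(0:(n / 2 - 1), 0, if (n > 2) -((n / 2 - 1):1) else NULL)
}

# Wavenumbers for even-order symbols (|k|^2, |k|^4): Nyquist kept at n/2.
full_wavenumbers <- function(n) {
  stopifnot(n %% 2L == 0L)
  c(0:(n / 2), if (n > 2) -((n / 2 - 1):1) else NULL)
}

# Wrap coordinates into the periodic domain [0, 2*pi). The modulo of a
# tiny negative number can round to exactly 2*pi; map that back to 0.
wrap_domain <- function(x) {
  r <- x %% (2 * pi)
  r[r >= 2 * pi] <- 0
  r
}

# Node coordinates of a grid as an N x d matrix in array (column-major) order.
grid_coords <- function(grid) {
  dims <- grid@dims
  d <- length(dims)
  out <- matrix(0, nrow = prod(dims), ncol = d)
  for (a in seq_len(d)) {
    ax <- (seq_len(dims[a]) - 1) * grid@spacing[a]
    out[, a] <- as.vector(axis_array(ax, dims, a))
  }
  out
}

# Uniform cubic B-spline kernel weights for the four nodes
# {i-1, i, i+1, i+2} at fractional offset t in [0,1). Partition of unity;
# applied to prefiltered coefficients this is C^2 interpolating-spline
# evaluation, exact at grid nodes and fourth-order accurate.
bspline3_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  omt <- 1 - t
  list(
    omt * omt * omt / 6,
    (3 * t3 - 6 * t2 + 4) / 6,
    (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
    t3 / 6
  )
}

# Periodic cubic B-spline prefilter: divide the spectrum by the B-spline
# symbol (4 + 2 cos(2*pi*k/n))/6 per axis, so that kernel evaluation of the
# coefficients interpolates the samples exactly. The symbol is bounded
# below by 1/3, so the division is well conditioned.
bspline3_prefilter <- function(vals, dims) {
  sym <- 1
  for (a in seq_along(dims)) {
    n <- dims[a]
    ba <- (4 + 2 * cos(2 * pi * (0:(n - 1)) / n)) / 6
    sym <- sym * axis_array(ba, dims, a)
  }
  ifftn_real(fftn(vals) / sym)
}

# Periodic tensor-product interpolation of an array at arbitrary points.
# vals: d-dimensional array; coords: N x d matrix of positions in [0, 2*pi);
# order 1 (multilinear) or 3 (cubic). Vectorized over points.
interp_core <- function(vals, coords, dims, spacing, order = 3L) {
  if (!all(is.finite(coords))) {
    stop("interpolation coordinates must be finite")
  }
  d <- length(dims)
  n_pts <- nrow(coords)
  s <- sweep(coords, 2, spacing, "/")      # real-valued 0-based index
  i0 <- floor(s)
  tfrac <- s - i0
  # numerical guard: t must lie in [0, 1)
  tfrac[tfrac < 0] <- 0
  tfrac[tfrac >= 1] <- 0

  if (order == 1L) {
    offsets <- 0:1
    wlist <- lapply(seq_len(d), function(a) {
      list(1 - tfrac[, a], tfrac[, a])
    })
  } else if (order == 3L) {
    offsets <- -1:2
    wlist <- lapply(seq_len(d), function(a) bspline3_weights(tfrac[, a]))
    vals <- bspline3_prefilter(vals, dims)
  } else {
    stop("interpolation order must be 1 or 3")
  }

  # 0-based wrapped indices per axis per stencil offset
  idx <- lapply(seq_len(d), function(a) {
    lapply(offsets, function(o) (i0[, a] + o) %% dims[a])
  })
  stride <- cumprod(c(1, dims[-d]))
  res <- numeric(n_pts)
  vals_vec <- as.vector(vals)
  combos <- as.matrix(expand.grid(rep(list(seq_along(offsets)), d)))
  for (r in seq_len(nrow(combos))) {
    lin <- 1
    w <- 1
    for (a in seq_len(d)) {
      oa <- combos[r, a]
      lin <- lin + idx[[a]][[oa]] * stride[a]
      w <- w * wlist[[a]][[oa]]
    }
    res <- res + w * vals_vec[lin]
  }
  res
}

# Discrete L2 inner product of two velocity fields (h^d-weighted).
velocity_inner <- function(u, w) {
  hd <- prod(u@grid@spacing)
  s <- 0
  for (a in seq_along(u@components)) {
    s <- s + sum(u@components[[a]] * w@components[[a]])
  }
  hd * s
}

velocity_norm <- function(u) sqrt(velocity_inner(u, u))

# Componentwise linear combination a*u + b*w of velocity fields.
velocity_axpy <- function(a, u, b, w) {
  comps <- lapply(seq_along(u@components), function(i) {
    a * u@components[[i]] + b * w@components[[i]]
  })
  new("VelocityField", grid = u@grid, components = comps)
}

velocity_scale <- function(a, u) {
  new("VelocityField", grid = u@grid,
      components = lapply(u@components, function(x) a * x))
}

zero_velocity <- function(grid) {
  d <- length(grid@dims)
  new("VelocityField", grid = grid,
      components = replicate(d, array(0, dim = grid@dims), simplify = FALSE))
}

max_velocity_magnitude <- function(v) {
  m2 <- 0
  for (comp in v@components) m2 <- m2 + comp^2
  sqrt(max(m2))
}

check_same_grid <- function(...) {
  objs <- list(...)
  ref <- objs[[1]]@grid@dims
  for (o in objs[-1]) {
    if (!identical(o@grid@dims, ref)) {
      stop("objects are defined on different grids")
    }
  }
  invisible(TRUE)
}
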