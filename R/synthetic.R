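# Synthetic registration problems with known ground truth. The template
# is a sum of periodic Gaussian bumps; the ground-truth velocity is a
# smooth band-limited random field (Fourier modes up to |k| <= 4 per
# axis, amplitudes decaying with |k|) rescaled to a prescribed maximum
# speed; the reference image is the template transported along that
# velocity with a high-accuracy (nt = 64) semi-Lagrangian solve. Every
# problem is reproducible bit-exactly from its seed.

# Smooth seeded random scalar field with spectrum limited to |k_a| <= kmax.
# Built as a sum of cosines over a half-plane of integer modes so the
# field is real; amplitudes ~ N(0,1) / (1 + |k|^2) favor smooth shapes.
# Consumes the current RNG stream.
random_band_limited_values <- function(grid, kmax = 4L) {
  dims <- grid@dims
  d <- length(dims)
  x <- grid_coords(grid)
  vals <- numeric(nrow(x))
  if (d == 2L) {
    modes <- expand.grid(k1 = 0:kmax, k2 = -kmax:kmax)
    modes <- modes[!(modes$k1 == 0 & modes$k2 < 0), ]
    modes <- modes[!(modes$k1 == 0 & modes$k2 == 0), ]
  } else {
    modes <- expand.grid(k1 = 0:kmax, k2 = -kmax:kmax, k3 = -kmax:kmax)
    modes <- modes[!(modes$k1 == 0 & (modes$k2 < 0 |
                     (modes$k2 == 0 & modes$k3 < 0))), ]
    modes <- modes[rowSums(abs(modes)) > 0, ]
  }
  for (r in seq_len(nrow(modes))) {
    k <- as.numeric(modes[r, ])
    amp <- stats::rnorm(1) / (1 + sum(k^2))
    phase <- stats::runif(1, 0, 2 * pi)
    vals <- vals + amp * cos(x %*% k + phase)
  }
  array(vals, dim = dims)
}

# Periodic Gaussian bump centered at `center` with width sigma: the
# squared distance uses the shortest periodic offset per axis.
periodic_bump <- function(grid, center, sigma) {
  x <- grid_coords(grid)
  d2 <- numeric(nrow(x))
  for (a in seq_len(ncol(x))) {
    off <- abs(x[, a] - center[a])
    off <- pmin(off, 2 * pi - off)
    d2 <- d2 + off^2
  }
  array(exp(-d2 / (2 * sigma^2)), dim = grid@dims)
}

#' Generate a synthetic registration problem
#'
#' Builds a template of \code{blobs} periodic Gaussian bumps (seeded
#' centers, widths and amplitudes, normalized to [0, 1]), a smooth
#' band-limited ground-truth velocity rescaled so that
#' \eqn{\max_x |v(x)| =} \code{magnitude}, and the reference image by
#' transporting the template along the velocity with \code{ntRef}
#' semi-Lagrangian steps. The ground-truth map is checked for a positive
#' Jacobian determinant at generation time; if violated, the velocity is
#' shrunk by 20\% repeatedly (and an error raised if that fails).
#' Fixed seeds give bit-identical problems; the caller's RNG state is
#' left untouched.
#'
#' @param seed integer seed.
#' @param dims grid dims (square/cubic, 2D or 3D); default \code{c(64, 64)}.
#' @param magnitude maximum pointwise speed of the ground-truth velocity
#'   (0 gives an identical image pair); default 0.3.
#' @param blobs number of Gaussian bumps in the template; default 3.
#' @param ntRef time steps of the high-accuracy transport; default 64.
#' @return a [SyntheticProblem-class].
#' @examples
#' prob <- generateSyntheticProblem(seed = 42, dims = c(32, 32),
#'                                  magnitude = 0.2)
#' prob
#' @export
generateSyntheticProblem <- function(seed, dims = c(64, 64), magnitude = 0.3,
                                     blobs = 3L, ntRef = 64L) {
  if (magnitude < 0) stop("magnitude must be nonnegative")
  if (length(unique(dims)) != 1L) stop("dims must be square/cubic")
  grid <- makeGrid(dims)
  d <- length(grid@dims)

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))

  tmpl <- array(0, dim = grid@dims)
  for (b in seq_len(blobs)) {
    center <- stats::runif(d, 0, 2 * pi)
    sigma <- stats::runif(1, 0.4, 0.9)
    amp <- stats::runif(1, 0.6, 1)
    tmpl <- tmpl + amp * periodic_bump(grid, center, sigma)
  }
  m0 <- normalizeIntensity(scalarField(grid, tmpl))

  comps <- replicate(d, random_band_limited_values(grid, kmax = 4L),
                     simplify = FALSE)
  v <- new("VelocityField", grid = grid, components = comps)
  vmax <- max_velocity_magnitude(v)
  if (magnitude == 0 || vmax == 0) {
    v <- zero_velocity(grid)
  } else {
    v <- velocity_scale(magnitude / vmax, v)
    # enforce a diffeomorphic ground truth
    for (try in seq_len(25L)) {
      detj <- jacobianDeterminant(computeDeformationMap(v, nt = 16L,
                                                        "forward"))
      if (min(detj@values) > 0) break
      if (try == 25L) {
        stop("could not rescale the ground-truth velocity to a diffeomorphism")
      }
      v <- velocity_scale(0.8, v)
    }
  }

  m1 <- if (magnitude == 0) {
    m0
  } else {
    traj <- solveState(m0, v, nt = as.integer(ntRef), interpOrder = 3L)
    trajectoryFrame(traj, length(traj@frames))
  }
  new("SyntheticProblem", m0 = m0, m1 = m1, vTrue = v,
      seed = as.integer(seed), magnitude = as.numeric(magnitude))
}
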