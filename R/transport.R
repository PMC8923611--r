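# Semi-Lagrangian solvers for the transport (state) equation
#   dm/dt + v . grad m = 0,  m(x, 0) = m0(x)
# and the adjoint continuity equation
#   -dl/dt - div(v l) = 0,   terminal condition at t = 1.
# Characteristics are traced with an RK2 (midpoint) rule; fields are
# evaluated at the characteristic feet by periodic tensor-product
# interpolation (cubic by default). The velocity is stationary, so the
# departure points of a fixed step size are computed once and reused.

# Interpolate each velocity component at arbitrary points -> N x d matrix.
interp_velocity <- function(v, coords, order = 3L) {
  grid <- v@grid
  out <- matrix(0, nrow = nrow(coords), ncol = length(v@components))
  for (a in seq_along(v@components)) {
    out[, a] <- interp_core(v@components[[a]], coords, grid@dims,
                            grid@spacing, order)
  }
  out
}

#' Trace semi-Lagrangian departure points
#'
#' For each grid node x, traces the characteristic of the stationary
#' velocity backward over one step with the RK2 midpoint rule:
#' \eqn{x^* = x - dt\, v(x - (dt/2) v(x))}, the midpoint velocity obtained
#' by periodic cubic interpolation. Exact for constant velocities.
#'
#' @param v a [VelocityField-class].
#' @param dt positive step size.
#' @param order interpolation order for the midpoint velocity (1 or 3).
#' @return a [DeparturePoints-class] with coordinates wrapped into
#'   \eqn{[0, 2\pi)}.
#' @export
traceDeparturePoints <- function(v, dt, order = 3L) {
  stopifnot(is(v, "VelocityField"))
  if (dt <= 0) stop("dt must be positive")
  if (dt * max_velocity_magnitude(v) > 2 * pi) {
    warning("characteristic displacement exceeds the domain extent; ",
            "accuracy will degrade")
  }
  grid <- v@grid
  x <- grid_coords(grid)
  vnode <- vapply(v@components, as.vector, numeric(nrow(x)))
  mid <- wrap_domain(x - (dt / 2) * vnode)
  vmid <- interp_velocity(v, mid, order)
  new("DeparturePoints", grid = grid, coords = wrap_domain(x - dt * vmid))
}

#' Periodic interpolation of a scalar field
#'
#' Evaluates a grid-sampled field at arbitrary points with periodic wrap in
#' every axis. Order 3 is periodic piecewise-cubic spline interpolation
#' (uniform cubic B-spline kernel on spectrally prefiltered coefficients:
#' C^2, fourth-order accurate); order 1 is multilinear. Both are exact at
#' grid nodes and linear in the field values.
#'
#' @param f a [ScalarField-class].
#' @param p a [DeparturePoints-class] (or a numeric matrix of positions in
#'   \eqn{[0, 2\pi)}, one row per point).
#' @param order 1 or 3 (default).
#' @return a [ScalarField-class] when \code{p} is a
#'   [DeparturePoints-class] (one value per node, arranged on the grid);
#'   a numeric vector of sampled values when \code{p} is a matrix.
#' @export
periodicInterpolate <- function(f, p, order = 3L) {
  stopifnot(is(f, "ScalarField"))
  coords <- if (is(p, "DeparturePoints")) p@coords else as.matrix(p)
  vals <- interp_core(f@values, coords, f@grid@dims, f@grid@spacing,
                      as.integer(order))
  if (is(p, "DeparturePoints")) {
    scalarField(f@grid, array(vals, dim = f@grid@dims))
  } else {
    vals
  }
}

#' Solve the transport (state) equation
#'
#' Advances \eqn{\partial_t m + v\cdot\nabla m = 0} from \eqn{m(0) = m_0}
#' over \eqn{t \in [0,1]} with \code{nt} semi-Lagrangian steps:
#' each new frame is the previous frame interpolated at the RK2 departure
#' points. The velocity is stationary, so the departure points are computed
#' once. Constants are preserved exactly, and with \code{interpOrder = 1}
#' the scheme satisfies a discrete maximum principle.
#'
#' @param m0 initial [ScalarField-class].
#' @param v stationary [VelocityField-class] on the same grid.
#' @param nt number of time steps (>= 1).
#' @param interpOrder 1 or 3 (default).
#' @return a [Trajectory-class] with nt+1 frames; frame 1 is \code{m0}.
#' @export
solveState <- function(m0, v, nt = 8L, interpOrder = 3L) {
  stopifnot(is(m0, "ScalarField"), is(v, "VelocityField"))
  check_same_grid(m0, v)
  nt <- as.integer(nt)
  if (nt < 1L) stop("nt must be >= 1")
  grid <- m0@grid
  dt <- 1 / nt
  dep <- traceDeparturePoints(v, dt, order = interpOrder)
  frames <- vector("list", nt + 1L)
  frames[[1L]] <- m0@values
  cur <- m0@values
  for (k in seq_len(nt)) {
    cur <- array(interp_core(cur, dep@coords, grid@dims, grid@spacing,
                             interpOrder), dim = grid@dims)
    frames[[k + 1L]] <- cur
  }
  new("Trajectory", grid = grid, times = seq(0, 1, length.out = nt + 1L),
      frames = frames)
}

# Per-step geometry of the backward-in-time adjoint solve: the adjoint
# characteristic through node x at time t_k reaches x + dt*v at t_{k+1}
# (RK2 via the forward midpoint), and the multiplier accumulates
# exp(int div v ds) along it, approximated by the midpoint rule.
adjoint_step_quantities <- function(v, dt, order = 3L) {
  grid <- v@grid
  x <- grid_coords(grid)
  vnode <- vapply(v@components, as.vector, numeric(nrow(x)))
  mid <- wrap_domain(x + (dt / 2) * vnode)
  vmid <- interp_velocity(v, mid, order)
  arrival <- wrap_domain(x + dt * vmid)
  q <- spectralDivergence(v)
  qmid <- interp_core(q@values, mid, grid@dims, grid@spacing, order)
  list(arrival = arrival, scale = array(exp(dt * qmid), dim = grid@dims))
}

#' Solve the adjoint (continuity) equation backward in time
#'
#' Integrates \eqn{-\partial_t \lambda - \nabla\cdot(v\lambda) = 0} from a
#' terminal condition at \eqn{t = 1} back to \eqn{t = 0}. Each backward step
#' follows the characteristic from node x forward to \eqn{x + dt\, v}
#' (RK2 midpoint trace), interpolates the later frame there, and scales by
#' \eqn{\exp(dt\, \nabla\cdot v)} evaluated at the characteristic midpoint
#' — the midpoint-rule quadrature of the compressibility source, second
#' order in time. For divergence-free v the scale is 1 and the scheme is
#' pure advection; the spatial integral of \eqn{\lambda} is conserved up to
#' discretization error (continuity-equation mass conservation).
#'
#' @param lambdaFinal terminal [ScalarField-class] at \eqn{t = 1}.
#' @param v stationary [VelocityField-class].
#' @param nt number of time steps.
#' @param interpOrder 1 or 3 (default).
#' @return a [Trajectory-class] ordered in increasing t; frame nt+1 is
#'   \code{lambdaFinal}.
#' @export
solveAdjoint <- function(lambdaFinal, v, nt = 8L, interpOrder = 3L) {
  stopifnot(is(lambdaFinal, "ScalarField"), is(v, "VelocityField"))
  check_same_grid(lambdaFinal, v)
  nt <- as.integer(nt)
  if (nt < 1L) stop("nt must be >= 1")
  grid <- v@grid
  dt <- 1 / nt
  geom <- adjoint_step_quantities(v, dt, order = interpOrder)
  frames <- vector("list", nt + 1L)
  frames[[nt + 1L]] <- lambdaFinal@values
  cur <- lambdaFinal@values
  for (k in nt:1) {
    cur <- geom$scale *
      array(interp_core(cur, geom$arrival, grid@dims, grid@spacing,
                        interpOrder), dim = grid@dims)
    frames[[k]] <- cur
  }
  new("Trajectory", grid = grid, times = seq(0, 1, length.out = nt + 1L),
      frames = frames)
}
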