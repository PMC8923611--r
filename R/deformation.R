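# Deformation maps generated by the stationary velocity flow, Jacobian
# determinant diagnostics, and image warping. Maps are stored as
# displacement fields relative to the identity (unwrapped), which keeps
# periodic wrapping unambiguous; the Jacobian uses spectral
# differentiation of the displacement, consistent with the rest of the
# solver.

#' Compute the deformation map of a stationary velocity
#'
#' Integrates the characteristics of v over \eqn{t \in [0,1]} with nt RK2
#' (midpoint) steps. The \code{"forward"} map is the pullback
#' \eqn{y(x)}: warping the template by it reproduces the transported
#' template, \eqn{m_0(y(x)) \approx m(x, 1)} (it follows the transport
#' characteristics backward, so for constant \eqn{v = (c, 0)} it is
#' \eqn{y(x) = x - (c, 0)}). The \code{"inverse"} map integrates the
#' opposite flow; composing the two returns the identity up to
#' discretization error.
#'
#' @param v a [VelocityField-class].
#' @param nt number of RK2 steps (>= 1).
#' @param direction "forward" (default) or "inverse".
#' @return a [DeformationMap-class].
#' @export
computeDeformationMap <- function(v, nt = 8L, direction = "forward") {
  stopifnot(is(v, "VelocityField"))
  nt <- as.integer(nt)
  if (nt < 1L) stop("nt must be >= 1")
  direction <- match.arg(direction, c("forward", "inverse"))
  sgn <- if (direction == "forward") -1 else 1
  grid <- v@grid
  dt <- 1 / nt
  x0 <- grid_coords(grid)
  p <- x0  # unwrapped positions
  for (k in seq_len(nt)) {
    vhere <- interp_velocity(v, wrap_domain(p), order = 3L)
    mid <- p + sgn * (dt / 2) * vhere
    vmid <- interp_velocity(v, wrap_domain(mid), order = 3L)
    p <- p + sgn * dt * vmid
  }
  disp <- p - x0
  displacement <- lapply(seq_len(ncol(disp)), function(a) {
    array(disp[, a], dim = grid@dims)
  })
  new("DeformationMap", grid = grid, displacement = displacement,
      direction = direction)
}

#' Jacobian determinant of a deformation map
#'
#' Computes \eqn{\det \nabla y} at every node, with
#' \eqn{\nabla y = I + \nabla u} and the displacement gradient taken
#' spectrally. The identity map gives 1 everywhere; positivity everywhere
#' is the discrete check that the map is a diffeomorphism (locally
#' one-to-one with positive orientation).
#'
#' @param y a [DeformationMap-class].
#' @return a [ScalarField-class] of determinant values.
#' @export
jacobianDeterminant <- function(y) {
  stopifnot(is(y, "DeformationMap"))
  grid <- y@grid
  d <- length(grid@dims)
  # J[[a]][[b]] = d y_a / d x_b = delta_ab + d u_a / d x_b
  J <- vector("list", d)
  for (a in seq_len(d)) {
    du <- spectralGradient(scalarField(grid, y@displacement[[a]]))
    J[[a]] <- du@components
    J[[a]][[a]] <- J[[a]][[a]] + 1
  }
  if (d == 2L) {
    det <- J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
  } else {
    det <- J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
           J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
           J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  }
  scalarField(grid, det)
}

#' Warp an image through a deformation map
#'
#' Evaluates \eqn{m(y(x))} by periodic interpolation of m at the mapped
#' positions. The identity map returns m exactly. Warping the template by
#' the forward map of a velocity agrees with transporting it by
#' [solveState()] up to discretization error (two numerical routes to the
#' same flow).
#'
#' @param m a [ScalarField-class].
#' @param y a [DeformationMap-class] on the same grid.
#' @param order interpolation order, 1 or 3 (default).
#' @return a [ScalarField-class].
#' @export
warpImage <- function(m, y, order = 3L) {
  stopifnot(is(m, "ScalarField"), is(y, "DeformationMap"))
  check_same_grid(m, y)
  grid <- m@grid
  x <- grid_coords(grid)
  disp <- vapply(y@displacement, as.vector, numeric(nrow(x)))
  coords <- wrap_domain(x + disp)
  scalarField(grid, array(
    interp_core(m@values, coords, grid@dims, grid@spacing,
                as.integer(order)),
    dim = grid@dims))
}
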