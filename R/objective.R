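# Objective functional of the registration problem
#   J(v) = (1/2) h^d sum (m(1) - m1)^2        (L2 image distance)
#        + (alpha/2) <A v, v>                 (Sobolev regularization)
#        + (gamma/2) h^d sum (div v)^2        (divergence penalty)
# and its reduced gradient
#   g = alpha A v - gamma grad(div v) + int_0^1 lambda grad m dt,
# with the adjoint lambda solved backward from lambda(1) = m1 - m(1).
# g is the gradient of the minimized J (descent direction is -g).

#' Squared L2 distance between two fields
#'
#' \eqn{(1/2) h^d \sum_x (a - b)^2}, the rectangle-rule quadrature of the
#' squared L2 norm of the mismatch (spectrally accurate on periodic fields).
#'
#' @param mFinal,m1 [ScalarField-class] objects on the same grid.
#' @return nonnegative scalar; 0 iff the fields are identical.
#' @export
l2Distance <- function(mFinal, m1) {
  stopifnot(is(mFinal, "ScalarField"), is(m1, "ScalarField"))
  check_same_grid(mFinal, m1)
  hd <- prod(mFinal@grid@spacing)
  0.5 * hd * sum((mFinal@values - m1@values)^2)
}

#' Sobolev regularization value
#'
#' \eqn{(\alpha/2)\langle A v, v\rangle} with A the operator of the
#' configured model ([regularizationApply()]). For the H1-seminorm this is
#' \eqn{(\alpha/2)\int |\nabla v|^2}, zero exactly when v is constant.
#'
#' @param v a [VelocityField-class].
#' @param cfg a [RegistrationConfig-class] (uses \code{regModel}, \code{alpha}).
#' @return nonnegative scalar.
#' @export
regularizationValue <- function(v, cfg) {
  stopifnot(is(v, "VelocityField"), is(cfg, "RegistrationConfig"))
  av <- regularizationApply(v, cfg@regModel)
  0.5 * cfg@alpha * velocity_inner(av, v)
}

#' Quadratic divergence penalty
#'
#' \eqn{(\gamma/2) h^d \sum_x (\nabla\cdot v)^2}: the quadratic-penalty
#' relaxation of a hard incompressibility constraint. Zero when
#' \eqn{\gamma = 0} or v is divergence-free.
#'
#' @param v a [VelocityField-class].
#' @param gamma nonnegative weight.
#' @return nonnegative scalar.
#' @export
divergencePenalty <- function(v, gamma) {
  stopifnot(is(v, "VelocityField"))
  if (gamma < 0) stop("gamma must be nonnegative")
  if (gamma == 0) return(0)
  q <- spectralDivergence(v)
  hd <- prod(v@grid@spacing)
  0.5 * gamma * hd * sum(q@values^2)
}

#' Evaluate the full registration objective
#'
#' Transports the template along v ([solveState()]) and sums the three
#' terms of the functional. Deterministic for a fixed configuration.
#'
#' @param v a [VelocityField-class].
#' @param m0,m1 template and reference [ScalarField-class] objects.
#' @param cfg a [RegistrationConfig-class].
#' @return an [ObjectiveReport-class].
#' @export
evaluateObjective <- function(v, m0, m1, cfg) {
  stopifnot(is(v, "VelocityField"), is(m0, "ScalarField"),
            is(m1, "ScalarField"), is(cfg, "RegistrationConfig"))
  check_same_grid(v, m0, m1)
  traj <- solveState(m0, v, cfg@nt, cfg@interpOrder)
  objective_from_trajectory(v, traj, m1, cfg)
}

# Assemble the report from an already-computed state trajectory.
objective_from_trajectory <- function(v, traj, m1, cfg) {
  dist <- l2Distance(trajectoryFrame(traj, length(traj@frames)), m1)
  reg <- regularizationValue(v, cfg)
  pen <- divergencePenalty(v, cfg@divGamma)
  new("ObjectiveReport", total = dist + reg + pen, distance = dist,
      regularization = reg, divPenalty = pen)
}

# Spectral gradients of every trajectory frame (list over time of lists
# over axes of arrays). Shared by the gradient and the Hessian matvec.
trajectory_gradients <- function(traj) {
  lapply(traj@frames, function(fr) {
    spectralGradient(scalarField(traj@grid, fr))@components
  })
}

# Trapezoidal time quadrature of the body force int lambda grad m dt,
# given the adjoint frames and the precomputed frame gradients.
body_force <- function(lambda_frames, grad_frames, grid, nt) {
  d <- length(grid@dims)
  dt <- 1 / nt
  comps <- replicate(d, array(0, dim = grid@dims), simplify = FALSE)
  for (k in seq_len(nt + 1L)) {
    wk <- if (k == 1L || k == nt + 1L) 0.5 else 1
    lam <- lambda_frames[[k]]
    for (a in seq_len(d)) {
      comps[[a]] <- comps[[a]] + wk * dt * lam * grad_frames[[k]][[a]]
    }
  }
  new("VelocityField", grid = grid, components = comps)
}

# -gamma * grad(div v): gradient of the divergence penalty.
div_penalty_gradient <- function(v, gamma) {
  if (gamma == 0) return(zero_velocity(v@grid))
  gq <- spectralGradient(spectralDivergence(v))
  velocity_scale(-gamma, gq)
}

#' Reduced gradient of the registration objective
#'
#' Computes the gradient of J with respect to the stationary velocity by
#' the adjoint-state method: solve the state equation forward, the adjoint
#' continuity equation backward from \eqn{\lambda(1) = m_1 - m(1)}, then
#' \deqn{g = \alpha A v - \gamma \nabla(\nabla\cdot v)
#'       + \int_0^1 \lambda \nabla m \, dt,}
#' the time integral by the trapezoidal rule over the nt+1 frames and
#' \eqn{\nabla m} per frame by spectral differentiation. At \eqn{v = 0}
#' with \eqn{m_0 = m_1} the gradient vanishes identically.
#'
#' @param v a [VelocityField-class].
#' @param m0,m1 template and reference [ScalarField-class] objects.
#' @param cfg a [RegistrationConfig-class].
#' @return a [VelocityField-class] holding g (ascent direction of J).
#' @export
reducedGradient <- function(v, m0, m1, cfg) {
  stopifnot(is(v, "VelocityField"), is(m0, "ScalarField"),
            is(m1, "ScalarField"), is(cfg, "RegistrationConfig"))
  check_same_grid(v, m0, m1)
  traj <- solveState(m0, v, cfg@nt, cfg@interpOrder)
  grad_frames <- trajectory_gradients(traj)
  reduced_gradient_core(v, traj, grad_frames, m1, cfg)
}

reduced_gradient_core <- function(v, traj, grad_frames, m1, cfg) {
  grid <- v@grid
  nt <- cfg@nt
  lambda1 <- scalarField(grid, m1@values - traj@frames[[nt + 1L]])
  lam <- solveAdjoint(lambda1, v, nt, cfg@interpOrder)
  body <- body_force(lam@frames, grad_frames, grid, nt)
  g <- velocity_axpy(cfg@alpha, regularizationApply(v, cfg@regModel), 1, body)
  if (cfg@divGamma > 0) {
    g <- velocity_axpy(1, g, 1, div_penalty_gradient(v, cfg@divGamma))
  }
  g
}
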