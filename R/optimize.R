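# Reduced-space Gauss-Newton-Krylov solver. The outer loop drives the
# reduced gradient to a relative tolerance; each search direction solves
# H p = -g by preconditioned conjugate gradients, where H is the
# Gauss-Newton Hessian applied matrix-free through the incremental state
# and adjoint equations, and the preconditioner is the inverse of the
# (shifted) regularization operator. Globalization is an Armijo
# backtracking line search.

# Per-linearization quantities reused by every Hessian matvec: the state
# trajectory, its spectral gradients per frame, the state departure points
# and the adjoint step geometry.
hessian_cache <- function(v, traj, grad_frames, cfg) {
  dt <- 1 / cfg@nt
  list(
    traj = traj,
    grad_frames = grad_frames,
    dep = traceDeparturePoints(v, dt, order = cfg@interpOrder),
    adj = adjoint_step_quantities(v, dt, order = cfg@interpOrder)
  )
}

# Backward continuity solve reusing precomputed step geometry.
adjoint_frames_from_geom <- function(lambda_final_values, geom, grid, nt,
                                     order) {
  frames <- vector("list", nt + 1L)
  frames[[nt + 1L]] <- lambda_final_values
  cur <- lambda_final_values
  for (k in nt:1) {
    cur <- geom$scale *
      array(interp_core(cur, geom$arrival, grid@dims, grid@spacing, order),
            dim = grid@dims)
    frames[[k]] <- cur
  }
  frames
}

gn_hessian_matvec_core <- function(w, v, cfg, cache) {
  grid <- v@grid
  nt <- cfg@nt
  dt <- 1 / nt
  d <- length(grid@dims)
  order <- cfg@interpOrder

  # body-force source b_k = w . grad m_k per frame
  b <- lapply(seq_len(nt + 1L), function(k) {
    acc <- array(0, dim = grid@dims)
    for (a in seq_len(d)) {
      acc <- acc + w@components[[a]] * cache$grad_frames[[k]][[a]]
    }
    acc
  })

  # incremental state: dm~/dt + v.grad m~ = -w.grad m, m~(0) = 0;
  # semi-Lagrangian step with trapezoidal source along the characteristic.
  mt <- array(0, dim = grid@dims)
  dep <- cache$dep@coords
  for (k in seq_len(nt)) {
    adv <- array(interp_core(mt, dep, grid@dims, grid@spacing, order),
                 dim = grid@dims)
    src_foot <- array(interp_core(b[[k]], dep, grid@dims, grid@spacing,
                                  order), dim = grid@dims)
    mt <- adv - (dt / 2) * (src_foot + b[[k + 1L]])
  }

  # incremental adjoint with terminal condition -m~(1), then assemble
  # H w = alpha A w - gamma grad(div w) + int lambda~ grad m dt.
  lam_frames <- adjoint_frames_from_geom(-mt, cache$adj, grid, nt, order)
  body <- body_force(lam_frames, cache$grad_frames, grid, nt)
  hw <- velocity_axpy(cfg@alpha, regularizationApply(w, cfg@regModel),
                      1, body)
  if (cfg@divGamma > 0) {
    hw <- velocity_axpy(1, hw, 1, div_penalty_gradient(w, cfg@divGamma))
  }
  hw
}

#' Gauss-Newton Hessian matrix-vector product
#'
#' Applies the reduced-space Gauss-Newton Hessian at the linearization
#' point v to a perturbation w: solve the incremental state equation
#' \eqn{\partial_t \tilde m + v\cdot\nabla\tilde m + w\cdot\nabla m = 0}
#' with \eqn{\tilde m(0) = 0}, then the incremental continuity (adjoint)
#' equation backward from \eqn{\tilde\lambda(1) = -\tilde m(1)}, and
#' assemble \eqn{H w = \alpha A w - \gamma\nabla(\nabla\cdot w) +
#' \int_0^1 \tilde\lambda \nabla m\, dt}. Linear in w, symmetric up to
#' discretization error, and positive semi-definite by construction
#' (Gauss-Newton drops the second-order constraint terms). When the
#' template is constant, \eqn{H w} reduces exactly to the regularization
#' and penalty terms.
#'
#' @param w perturbation [VelocityField-class].
#' @param state the [Trajectory-class] of the state at v (from
#'   [solveState()] with the same cfg).
#' @param v linearization-point [VelocityField-class].
#' @param cfg a [RegistrationConfig-class].
#' @return a [VelocityField-class], \eqn{H w}.
#' @export
gnHessianMatvec <- function(w, state, v, cfg) {
  stopifnot(is(w, "VelocityField"), is(state, "Trajectory"),
            is(v, "VelocityField"), is(cfg, "RegistrationConfig"))
  check_same_grid(w, v)
  cache <- hessian_cache(v, state, trajectory_gradients(state), cfg)
  gn_hessian_matvec_core(w, v, cfg, cache)
}

#' Preconditioned conjugate-gradient solve
#'
#' Standard PCG on velocity fields under the discrete L2 inner product.
#' Iterates until the preconditioned residual norm drops below \code{tol}
#' times its initial value or \code{maxit} is reached. If a direction of
#' nonpositive curvature is detected the solve truncates and returns the
#' current iterate flagged with \code{negCurvature = TRUE} (falling back to
#' the preconditioned right-hand side if no step was taken yet).
#'
#' @param matvec function taking and returning a [VelocityField-class]
#'   (symmetric positive definite up to tolerance).
#' @param rhs right-hand-side [VelocityField-class].
#' @param precond function applying the preconditioner (symmetric positive
#'   definite); defaults to the identity.
#' @param tol relative tolerance in (0, 1).
#' @param maxit maximum iterations.
#' @return list with \code{solution} ([VelocityField-class]),
#'   \code{iterations}, \code{converged}, \code{negCurvature}, and
#'   \code{residuals} (preconditioned residual norms, starting at
#'   iteration 0).
#' @export
pcgSolve <- function(matvec, rhs, precond = identity, tol = 1e-1,
                     maxit = 50L) {
  stopifnot(is(rhs, "VelocityField"))
  if (tol <= 0 || tol >= 1) stop("tol must lie in (0, 1)")
  x <- zero_velocity(rhs@grid)
  r <- rhs
  rnorm0 <- velocity_norm(r)
  if (rnorm0 == 0) {
    return(list(solution = x, iterations = 0L, converged = TRUE,
                negCurvature = FALSE, residuals = 0))
  }
  z <- precond(r)
  rz <- velocity_inner(r, z)
  res0 <- sqrt(max(rz, 0))
  residuals <- res0
  p <- z
  neg <- FALSE
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    hp <- matvec(p)
    php <- velocity_inner(p, hp)
    if (php <= 0) {
      neg <- TRUE
      if (velocity_norm(x) == 0) x <- z
      it <- it - 1L
      break
    }
    a <- rz / php
    x <- velocity_axpy(1, x, a, p)
    r <- velocity_axpy(1, r, -a, hp)
    z <- precond(r)
    rz_new <- velocity_inner(r, z)
    res <- sqrt(max(rz_new, 0))
    residuals <- c(residuals, res)
    if (res <= tol * res0) {
      converged <- TRUE
      break
    }
    p <- velocity_axpy(1, z, rz_new / rz, p)
    rz <- rz_new
  }
  list(solution = x, iterations = it, converged = converged,
       negCurvature = neg, residuals = residuals)
}

#' Armijo backtracking line search
#'
#' Starting from a unit step, halves the step until the sufficient-decrease
#' condition \eqn{J(v + s p) \le J_0 + c_1 s \langle g, p\rangle} holds.
#' Requires p to be a descent direction (\eqn{\langle g, p\rangle < 0}).
#'
#' @param v current [VelocityField-class].
#' @param p search-direction [VelocityField-class].
#' @param g gradient [VelocityField-class] at v.
#' @param J0 objective value at v.
#' @param evalFn function mapping a velocity field to the objective value.
#' @param c1 Armijo constant in (0, 0.5).
#' @param maxit maximum halvings.
#' @return list with \code{step} (in \eqn{\{1, 1/2, 1/4, \dots\}}),
#'   \code{objective} at the accepted point, and \code{ok} (FALSE when
#'   maxit halvings were exhausted without sufficient decrease).
#' @export
armijoLineSearch <- function(v, p, g, J0, evalFn, c1 = 1e-4, maxit = 20L) {
  stopifnot(is(v, "VelocityField"), is(p, "VelocityField"),
            is(g, "VelocityField"))
  if (c1 <= 0 || c1 >= 0.5) stop("c1 must lie in (0, 0.5)")
  gp <- velocity_inner(g, p)
  if (gp >= 0) stop("line-search direction is not a descent direction")
  s <- 1
  for (i in seq_len(maxit)) {
    Jtrial <- evalFn(velocity_axpy(1, v, s, p))
    if (Jtrial <= J0 + c1 * s * gp) {
      return(list(step = s, objective = Jtrial, ok = TRUE))
    }
    s <- s / 2
  }
  list(step = s, objective = NA_real_, ok = FALSE)
}

#' Register two images
#'
#' Solves the PDE-constrained registration problem with a reduced-space
#' Gauss-Newton-Krylov method: starting from \eqn{v = 0}, each outer
#' iteration evaluates the objective and reduced gradient, solves
#' \eqn{H p = -g} by PCG preconditioned with the inverse shifted
#' regularization operator, and takes an Armijo step. The loop stops when
#' the gradient norm has dropped below \code{outerTol} times its initial
#' value or after \code{outerMaxit} iterations. The result records the
#' convergence history, the final forward deformation map, its minimum
#' Jacobian determinant (the discrete diffeomorphism check), and the ratio
#' of final to initial L2 mismatch.
#'
#' @param m0 template [ScalarField-class] (intensities in [0, 1]; see
#'   [normalizeIntensity()]).
#' @param m1 reference [ScalarField-class] on the same grid.
#' @param cfg a [RegistrationConfig-class].
#' @param verbose print one line per outer iteration.
#' @return a [RegistrationResult-class].
#' @examples
#' \donttest{
#' prob <- generateSyntheticProblem(seed = 1, dims = c(32, 32),
#'                                  magnitude = 0.2)
#' res <- registerImages(prob@m0, prob@m1,
#'                       registrationConfig(outerMaxit = 10))
#' res
#' }
#' @export
registerImages <- function(m0, m1, cfg = registrationConfig(),
                           verbose = FALSE) {
  stopifnot(is(m0, "ScalarField"), is(m1, "ScalarField"),
            is(cfg, "RegistrationConfig"))
  check_same_grid(m0, m1)
  grid <- m0@grid
  v <- zero_velocity(grid)
  dist0 <- l2Distance(m0, m1)

  eval_at <- function(vv) {
    traj <- solveState(m0, vv, cfg@nt, cfg@interpOrder)
    list(traj = traj, report = objective_from_trajectory(vv, traj, m1, cfg))
  }
  cur <- eval_at(v)
  grad_frames <- trajectory_gradients(cur$traj)
  g <- reduced_gradient_core(v, cur$traj, grad_frames, m1, cfg)
  gnorm0 <- velocity_norm(g)
  gnorm <- gnorm0

  history <- data.frame(index = 0L, objective = cur$report@total,
                        gradientNorm = gnorm, stepLength = NA_real_,
                        krylovIters = 0L)
  if (verbose) {
    message(sprintf("it %3d  J = %.6e  |g| = %.3e", 0L, cur$report@total,
                    gnorm))
  }
  # relative gradient rule, with an absolute floor so that an already
  # vanishing gradient (identical images) stops at iteration 0
  gtarget <- function(gn) gn <= max(cfg@outerTol * gnorm0, 1e-14)
  converged <- gtarget(gnorm)
  precond <- function(r) {
    regularizationInverse(r, cfg@regModel, cfg@alpha, cfg@precondShift)
  }

  it <- 0L
  while (!converged && it < cfg@outerMaxit) {
    it <- it + 1L
    cache <- hessian_cache(v, cur$traj, grad_frames, cfg)
    matvec <- function(w) gn_hessian_matvec_core(w, v, cfg, cache)
    pcg <- pcgSolve(matvec, velocity_scale(-1, g), precond,
                    tol = cfg@krylovTol, maxit = cfg@krylovMaxit)
    p <- pcg$solution
    if (velocity_inner(g, p) >= 0) {
      # safeguard: fall back to preconditioned steepest descent
      p <- precond(velocity_scale(-1, g))
    }
    ls <- armijoLineSearch(v, p, g, cur$report@total,
                           function(vv) {
                             evaluateObjective(vv, m0, m1, cfg)@total
                           },
                           c1 = cfg@lsC1, maxit = cfg@lsMaxit)
    if (!ls$ok) {
      warning("line search failed; returning best iterate")
      break
    }
    v <- velocity_axpy(1, v, ls$step, p)
    cur <- eval_at(v)
    grad_frames <- trajectory_gradients(cur$traj)
    g <- reduced_gradient_core(v, cur$traj, grad_frames, m1, cfg)
    gnorm <- velocity_norm(g)
    history <- rbind(history, data.frame(
      index = it, objective = cur$report@total, gradientNorm = gnorm,
      stepLength = ls$step, krylovIters = pcg$iterations))
    if (verbose) {
      message(sprintf("it %3d  J = %.6e  |g| = %.3e  step %.3g  krylov %d",
                      it, cur$report@total, gnorm, ls$step, pcg$iterations))
    }
    converged <- gtarget(gnorm)
  }

  map <- computeDeformationMap(v, cfg@nt, "forward")
  detj <- jacobianDeterminant(map)
  ratio <- if (dist0 == 0) 1 else cur$report@distance / dist0
  new("RegistrationResult", velocity = v, map = map, history = history,
      converged = converged, finalMismatchRatio = ratio,
      minJacobianDet = min(detj@values), config = cfg)
}
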