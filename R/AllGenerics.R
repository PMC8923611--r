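# Constructors, accessor generics, and show methods for the core classes.

#' Construct a periodic grid
#'
#' @param dims integer vector of grid points per axis (2 or 3 axes, each
#'   even and >= 4). The domain is always \eqn{[0, 2\pi)^d}.
#' @return a [Grid-class].
#' @examples
#' g <- makeGrid(c(16, 16))
#' gridDims(g)
#' @export
makeGrid <- function(dims) {
  dims <- as.integer(dims)
  d <- length(dims)
  if (!(d %in% c(2L, 3L))) stop("grid must have 2 or 3 axes")
  if (any(dims < 4L)) stop("all grid dims must be >= 4")
  if (any(dims %% 2L != 0L)) stop("all grid dims must be even")
  spacing <- 2 * pi / dims
  kderiv <- lapply(seq_len(d), function(a) {
    axis_array(deriv_wavenumbers(dims[a]), dims, a)
  })
  ksq <- Reduce(`+`, lapply(seq_len(d), function(a) {
    axis_array(full_wavenumbers(dims[a])^2, dims, a)
  }))
  new("Grid", dims = dims, spacing = spacing, kderiv = kderiv, ksq = ksq)
}

#' Construct a scalar field
#'
#' @param grid a [Grid-class].
#' @param values numeric array shaped like the grid (a matrix in 2D); a
#'   single number is recycled into a constant field.
#' @return a [ScalarField-class].
#' @export
scalarField <- function(grid, values) {
  if (length(values) == 1L) {
    values <- array(as.numeric(values), dim = grid@dims)
  }
  if (length(values) != prod(grid@dims)) {
    stop("value array shape must equal grid dims")
  }
  new("ScalarField", grid = grid, values = array(as.numeric(values),
                                                 dim = grid@dims))
}

#' Construct a velocity field
#'
#' @param grid a [Grid-class].
#' @param components list of d numeric arrays (one per axis), each shaped
#'   like the grid, or [ScalarField-class] objects.
#' @return a [VelocityField-class].
#' @export
velocityField <- function(grid, components) {
  comps <- lapply(components, function(comp) {
    if (is(comp, "ScalarField")) comp <- comp@values
    array(as.numeric(comp), dim = grid@dims)
  })
  new("VelocityField", grid = grid, components = comps)
}

#' Construct a registration configuration
#'
#' Defaults follow a single-level Gauss-Newton-Krylov solve with an
#' H1-seminorm regularizer: \code{alpha = 1e-2}, \code{divGamma = 0},
#' \code{nt = 8}, cubic interpolation, \code{outerTol = 5e-2},
#' \code{outerMaxit = 50}, \code{krylovTol = 1e-1}, \code{krylovMaxit = 50},
#' \code{lsC1 = 1e-4}, \code{lsMaxit = 20}, \code{precondShift = 1}.
#'
#' @param regModel "h1s", "h1" or "h2s".
#' @param alpha positive regularization weight.
#' @param divGamma nonnegative divergence-penalty weight.
#' @param nt semi-Lagrangian time steps.
#' @param interpOrder 1 or 3.
#' @param outerTol relative gradient reduction for convergence, in (0,1).
#' @param outerMaxit maximum outer iterations.
#' @param krylovTol inner PCG relative tolerance, in (0,1).
#' @param krylovMaxit maximum PCG iterations.
#' @param lsC1 Armijo constant, in (0, 0.5).
#' @param lsMaxit maximum line-search halvings.
#' @param precondShift positive shift in the spectral preconditioner.
#' @return a [RegistrationConfig-class].
#' @export
registrationConfig <- function(regModel = "h1s", alpha = 1e-2, divGamma = 0,
                               nt = 8L, interpOrder = 3L, outerTol = 5e-2,
                               outerMaxit = 50L, krylovTol = 1e-1,
                               krylovMaxit = 50L, lsC1 = 1e-4, lsMaxit = 20L,
                               precondShift = 1) {
  new("RegistrationConfig", regModel = regModel, alpha = alpha,
      divGamma = divGamma, nt = as.integer(nt),
      interpOrder = as.integer(interpOrder), outerTol = outerTol,
      outerMaxit = as.integer(outerMaxit), krylovTol = krylovTol,
      krylovMaxit = as.integer(krylovMaxit), lsC1 = lsC1,
      lsMaxit = as.integer(lsMaxit), precondShift = precondShift)
}

#' @title Accessors for grids and fields
#' @description \code{gridDims} returns the integer grid dimensions;
#'   \code{gridSpacing} the node spacing per axis; \code{gridOf} the
#'   underlying [Grid-class] of a field-like object; \code{fieldValues} the
#'   value array of a [ScalarField-class]; \code{velocityComponent} one
#'   component of a [VelocityField-class] as a scalar field;
#'   \code{trajectoryFrame} one time slice of a [Trajectory-class].
#' @param x object to access.
#' @param i component / frame index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' @rdname accessors
#' @export
setMethod("gridOf", "ScalarField", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "VelocityField", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "Trajectory", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "DeformationMap", function(x) x@grid)

#' @rdname accessors
#' @export
gridDims <- function(x) {
  if (is(x, "Grid")) x@dims else gridOf(x)@dims
}

#' @rdname accessors
#' @export
gridSpacing <- function(x) {
  if (is(x, "Grid")) x@spacing else gridOf(x)@spacing
}

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)

#' @rdname accessors
#' @export
velocityComponent <- function(x, i) {
  stopifnot(is(x, "VelocityField"))
  scalarField(x@grid, x@components[[i]])
}

#' @rdname accessors
#' @export
trajectoryFrame <- function(x, i) {
  stopifnot(is(x, "Trajectory"))
  scalarField(x@grid, x@frames[[i]])
}

#' @rdname accessors
#' @export
trajectoryTimes <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@times
}

setMethod("show", "Grid", function(object) {
  cat(sprintf("Periodic grid on [0, 2*pi)^%d: %s nodes, spacing %s\n",
              length(object@dims), paste(object@dims, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = ", ")))
})

setMethod("show", "ScalarField", function(object) {
  cat(sprintf("ScalarField on %s grid: range [%.4g, %.4g]\n",
              paste(object@grid@dims, collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf("VelocityField on %s grid: max |v| = %.4g\n",
              paste(object@grid@dims, collapse = " x "),
              max_velocity_magnitude(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames on t in [%g, %g], %s grid\n",
              length(object@frames), min(object@times), max(object@times),
              paste(object@grid@dims, collapse = " x ")))
})

setMethod("show", "ObjectiveReport", function(object) {
  cat(sprintf(
    "Objective: total %.6g = distance %.6g + regularization %.6g + divPenalty %.6g\n",
    object@total, object@distance, object@regularization, object@divPenalty))
})

setMethod("show", "RegistrationConfig", function(object) {
  cat(sprintf(
    "RegistrationConfig: %s, alpha = %g, gamma = %g, nt = %d, interp order %d\n",
    object@regModel, object@alpha, object@divGamma, object@nt,
    object@interpOrder))
  cat(sprintf(
    "  outer: tol %g, maxit %d | PCG: tol %g, maxit %d | Armijo: c1 %g, maxit %d\n",
    object@outerTol, object@outerMaxit, object@krylovTol, object@krylovMaxit,
    object@lsC1, object@lsMaxit))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult: %d outer iterations, converged = %s\n",
    nrow(object@history), object@converged))
  cat(sprintf("  final/initial L2 mismatch: %.4g\n",
              object@finalMismatchRatio))
  cat(sprintf("  min det(Jacobian) of forward map: %.4g\n",
              object@minJacobianDet))
})

setMethod("show", "SyntheticProblem", function(object) {
  cat(sprintf(
    "SyntheticProblem (seed %d): %s grid, ground-truth max |v| = %.3g\n",
    object@seed, paste(object@m0@grid@dims, collapse = " x "),
    object@magnitude))
})

#' @rdname accessors
#' @export
registrationHistory <- function(x) {
  stopifnot(is(x, "RegistrationResult"))
  x@history
}

#' @rdname accessors
#' @export
registrationVelocity <- function(x) {
  stopifnot(is(x, "RegistrationResult"))
  x@velocity
}
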