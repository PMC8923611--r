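#' @import methods
NULL

#' Periodic grid geometry
#'
#' A \code{Grid} describes a regular periodic grid on the fixed domain
#' \eqn{[0, 2\pi)^d} with \eqn{d = 2} or \eqn{3} axes. The node spacing is
#' \eqn{2\pi / n_a} per axis, and the grid carries the signed integer
#' wavenumbers used by all spectral (FFT-based) operators: first-derivative
#' wavenumbers with the Nyquist mode zeroed, and the \eqn{|k|^2} symbol with
#' the Nyquist mode retained.
#'
#' @slot dims integer vector of grid points per axis; each must be even and
#'   at least 4.
#' @slot spacing numeric vector, \code{2*pi/dims}.
#' @slot kderiv list of d arrays holding the per-node derivative wavenumber
#'   along each axis (Nyquist zeroed).
#' @slot ksq array of \eqn{\sum_a k_a^2} per node (negative Laplacian symbol).
#'
#' @seealso [makeGrid()]
#' @export
setClass("Grid",
  representation(
    dims = "integer",
    spacing = "numeric",
    kderiv = "list",
    ksq = "array"
  ),
  validity = function(object) {
    d <- length(object@dims)
    if (!(d %in% c(2L, 3L))) return("grid must have 2 or 3 axes")
    if (any(object@dims < 4L)) return("all grid dims must be >= 4")
    if (any(object@dims %% 2L != 0L)) return("all grid dims must be even")
    if (max(abs(object@spacing * object@dims - 2 * pi)) > 1e-12) {
      return("spacing * dims must equal 2*pi per axis")
    }
    TRUE
  }
)

#' Scalar field sampled on a periodic grid
#'
#' Holds one real sample per grid node: an image (template \eqn{m_0},
#' reference \eqn{m_1}, or transported intensity \eqn{m(\cdot,t)}), an
#' adjoint variable, or any other scalar diagnostic.
#'
#' @slot grid a [Grid-class].
#' @slot values numeric array with \code{dim(values) == dims(grid)}; all
#'   values finite.
#'
#' @seealso [scalarField()], [fieldValues()]
#' @export
setClass("ScalarField",
  representation(grid = "Grid", values = "array"),
  validity = function(object) {
    if (!identical(as.integer(dim(object@values)), object@grid@dims)) {
      return("value array shape must equal grid dims")
    }
    if (!all(is.finite(object@values))) return("field values must be finite")
    TRUE
  }
)

#' Stationary velocity field
#'
#' The control variable of the registration problem: a time-independent
#' vector field \eqn{v(x)} with one component per axis, in units of domain
#' length per unit flow time (the flow runs over \eqn{t \in [0,1]}).
#'
#' @slot grid a [Grid-class].
#' @slot components list of d numeric arrays, one per axis, each shaped like
#'   the grid; all values finite.
#'
#' @seealso [velocityField()], [velocityComponent()]
#' @export
setClass("VelocityField",
  representation(grid = "Grid", components = "list"),
  validity = function(object) {
    d <- length(object@grid@dims)
    if (length(object@components) != d) {
      return("one component per grid axis required")
    }
    for (comp in object@components) {
      if (!identical(as.integer(dim(comp)), object@grid@dims)) {
        return("component shape must equal grid dims")
      }
      if (!all(is.finite(comp))) return("component values must be finite")
    }
    TRUE
  }
)

#' Time trajectory of a transported scalar field
#'
#' Stores the nt+1 time slices \eqn{m(\cdot, t_k)} of a semi-Lagrangian
#' solve on the uniform time grid \eqn{t_k = k/nt}, \eqn{t \in [0,1]}.
#' \code{frames[[1]]} is the slice at \eqn{t = 0}.
#'
#' @slot grid a [Grid-class].
#' @slot times numeric vector of nt+1 strictly increasing time samples.
#' @slot frames list of nt+1 numeric arrays, one per time sample.
#'
#' @export
setClass("Trajectory",
  representation(grid = "Grid", times = "numeric", frames = "list"),
  validity = function(object) {
    if (length(object@times) < 2) return("need at least two time samples")
    if (any(diff(object@times) <= 0)) {
      return("times must be strictly increasing")
    }
    if (length(object@frames) != length(object@times)) {
      return("one frame per time sample required")
    }
    TRUE
  }
)

#' Departure points of semi-Lagrangian characteristics
#'
#' For each grid node \eqn{x}, the position at the foot of the backward
#' characteristic over one time step, wrapped into the periodic domain.
#'
#' @slot grid a [Grid-class].
#' @slot coords numeric matrix, \code{prod(dims)} rows by d columns, entries
#'   in \eqn{[0, 2\pi)}, in array (column-major) node order.
#'
#' @seealso [traceDeparturePoints()]
#' @export
setClass("DeparturePoints",
  representation(grid = "Grid", coords = "matrix"),
  validity = function(object) {
    if (nrow(object@coords) != prod(object@grid@dims) ||
        ncol(object@coords) != length(object@grid@dims)) {
      return("coords must be prod(dims) x d")
    }
    if (!all(is.finite(object@coords))) return("coords must be finite")
    if (any(object@coords < 0) || any(object@coords >= 2 * pi)) {
      return("coords must lie in [0, 2*pi)")
    }
    TRUE
  }
)

#' Deformation map
#'
#' The spatial correspondence \eqn{y(x)} generated by flowing the stationary
#' velocity over \eqn{t \in [0,1]}. Stored as an unwrapped displacement
#' relative to the identity so that periodic wrapping stays unambiguous:
#' \code{y(x) = x + displacement(x)}. With \code{direction = "forward"} the
#' map is the pullback satisfying \eqn{m_0(y(x)) \approx} the transported
#' template at \eqn{t = 1}; \code{"inverse"} integrates the opposite flow.
#'
#' @slot grid a [Grid-class].
#' @slot displacement list of d numeric arrays (unwrapped displacement per
#'   axis).
#' @slot direction \code{"forward"} or \code{"inverse"}.
#'
#' @seealso [computeDeformationMap()], [jacobianDeterminant()], [warpImage()]
#' @export
setClass("DeformationMap",
  representation(grid = "Grid", displacement = "list", direction = "character"),
  validity = function(object) {
    if (!(object@direction %in% c("forward", "inverse"))) {
      return("direction must be 'forward' or 'inverse'")
    }
    if (length(object@displacement) != length(object@grid@dims)) {
      return("one displacement component per axis required")
    }
    for (comp in object@displacement) {
      if (!all(is.finite(comp))) return("displacement must be finite")
      if (!identical(as.integer(dim(comp)), object@grid@dims)) {
        return("displacement shape must equal grid dims")
      }
    }
    TRUE
  }
)

#' Registration configuration
#'
#' All tunables of the variational problem and of the Gauss-Newton-Krylov
#' solver. Construct with [registrationConfig()], which documents defaults.
#'
#' @slot regModel regularization model: \code{"h1s"} (H1-seminorm, default),
#'   \code{"h1"} (full H1 norm) or \code{"h2s"} (H2-seminorm).
#' @slot alpha positive regularization weight \eqn{\alpha}.
#' @slot divGamma nonnegative weight of the quadratic divergence penalty.
#' @slot nt number of semi-Lagrangian time steps over \eqn{[0,1]}.
#' @slot interpOrder interpolation order, 1 (linear) or 3 (cubic).
#' @slot outerTol relative gradient-norm reduction for outer convergence.
#' @slot outerMaxit maximum outer (Gauss-Newton) iterations.
#' @slot krylovTol relative tolerance of the inner PCG solve.
#' @slot krylovMaxit maximum PCG iterations.
#' @slot lsC1 Armijo sufficient-decrease constant.
#' @slot lsMaxit maximum step halvings in the line search.
#' @slot precondShift positive shift added to \eqn{\alpha A} in the
#'   preconditioner (keeps the seminorm inverse nonsingular on constants).
#'
#' @export
setClass("RegistrationConfig",
  representation(
    regModel = "character",
    alpha = "numeric",
    divGamma = "numeric",
    nt = "integer",
    interpOrder = "integer",
    outerTol = "numeric",
    outerMaxit = "integer",
    krylovTol = "numeric",
    krylovMaxit = "integer",
    lsC1 = "numeric",
    lsMaxit = "integer",
    precondShift = "numeric"
  ),
  validity = function(object) {
    if (!(object@regModel %in% c("h1s", "h1", "h2s"))) {
      return("regModel must be one of 'h1s', 'h1', 'h2s'")
    }
    if (object@alpha <= 0) return("alpha must be positive")
    if (object@divGamma < 0) return("divGamma must be nonnegative")
    if (object@nt < 1L) return("nt must be >= 1")
    if (!(object@interpOrder %in% c(1L, 3L))) {
      return("interpOrder must be 1 or 3")
    }
    if (object@outerTol <= 0 || object@outerTol >= 1) {
      return("outerTol must lie in (0, 1)")
    }
    if (object@krylovTol <= 0 || object@krylovTol >= 1) {
      return("krylovTol must lie in (0, 1)")
    }
    if (object@lsC1 <= 0 || object@lsC1 >= 0.5) {
      return("lsC1 must lie in (0, 0.5)")
    }
    if (object@precondShift <= 0) return("precondShift must be positive")
    TRUE
  }
)

#' Decomposition of the objective functional
#'
#' The value of the minimized functional and its three terms: the squared
#' L2 image distance at \eqn{t = 1}, the Sobolev regularization
#' \eqn{(\alpha/2)\langle A v, v\rangle}, and the quadratic divergence
#' penalty. \code{total = distance + regularization + divPenalty}.
#'
#' @slot total numeric.
#' @slot distance numeric.
#' @slot regularization numeric.
#' @slot divPenalty numeric.
#'
#' @seealso [evaluateObjective()]
#' @export
setClass("ObjectiveReport",
  representation(
    total = "numeric",
    distance = "numeric",
    regularization = "numeric",
    divPenalty = "numeric"
  ),
  validity = function(object) {
    vals <- c(object@total, object@distance, object@regularization,
              object@divPenalty)
    if (!all(is.finite(vals))) return("all terms must be finite")
    if (any(vals < -1e-12)) return("all terms must be nonnegative")
    ref <- max(1, abs(object@total))
    if (abs(object@total - (object@distance + object@regularization +
                            object@divPenalty)) > 1e-9 * ref) {
      return("total must equal the sum of the three terms")
    }
    TRUE
  }
)

#' Result of a registration run
#'
#' @slot velocity the optimized stationary [VelocityField-class].
#' @slot map the final forward [DeformationMap-class].
#' @slot history data.frame with one row per outer iteration: \code{index},
#'   \code{objective}, \code{gradientNorm}, \code{stepLength},
#'   \code{krylovIters}.
#' @slot converged logical; TRUE when the relative gradient criterion was met.
#' @slot finalMismatchRatio final / initial L2 distance (1 by convention when
#'   the images already coincide).
#' @slot minJacobianDet minimum over nodes of det of the Jacobian of the
#'   final forward map; positivity is the discrete diffeomorphism check.
#' @slot config the [RegistrationConfig-class] used.
#'
#' @seealso [registerImages()]
#' @export
setClass("RegistrationResult",
  representation(
    velocity = "VelocityField",
    map = "DeformationMap",
    history = "data.frame",
    converged = "logical",
    finalMismatchRatio = "numeric",
    minJacobianDet = "numeric",
    config = "RegistrationConfig"
  ),
  validity = function(object) {
    if (nrow(object@history) < 1) return("history must be nonempty")
    if (object@finalMismatchRatio < 0) {
      return("finalMismatchRatio must be >= 0")
    }
    TRUE
  }
)

#' Synthetic registration problem with known ground truth
#'
#' A template made of periodic Gaussian bumps, a smooth band-limited
#' ground-truth velocity, and the reference image obtained by high-accuracy
#' transport of the template along that velocity.
#'
#' @slot m0 template [ScalarField-class].
#' @slot m1 reference [ScalarField-class] (transport of m0 along vTrue).
#' @slot vTrue ground-truth [VelocityField-class].
#' @slot seed integer seed that reproduces the problem bit-exactly.
#' @slot magnitude max pointwise speed of vTrue.
#'
#' @seealso [generateSyntheticProblem()]
#' @export
setClass("SyntheticProblem",
  representation(
    m0 = "ScalarField",
    m1 = "ScalarField",
    vTrue = "VelocityField",
    seed = "integer",
    magnitude = "numeric"
  ),
  validity = function(object) {
    if (object@magnitude < 0) return("magnitude must be nonnegative")
    TRUE
  }
)
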