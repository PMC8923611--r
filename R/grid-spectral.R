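# FFT-based differential and Sobolev operators on the periodic grid.
# Differentiation multiplies the spectrum by i*k per axis (Nyquist-mode
# first derivative zeroed, the standard even-grid convention); the Sobolev
# operators are diagonal in Fourier space with symbols |k|^2 (h1s),
# |k|^2 + 1 (h1) and |k|^4 (h2s).

reg_symbol <- function(grid, model) {
  switch(model,
    h1s = grid@ksq,
    h1 = grid@ksq + 1,
    h2s = grid@ksq^2,
    stop(sprintf("unknown regularization model '%s'", model))
  )
}

#' Spectral gradient of a scalar field
#'
#' Exact (band-limited) partial derivatives via the FFT: each component a
#' is the inverse transform of \eqn{i k_a \hat f}. The result of a real
#' input is real; the imaginary rounding residue is discarded.
#'
#' @param f a [ScalarField-class] with finite values.
#' @return a [VelocityField-class] holding one derivative per axis.
#' @examples
#' g <- makeGrid(c(16, 16))
#' x1 <- (seq_len(16) - 1) * gridSpacing(g)[1]
#' f <- scalarField(g, outer(sin(x1), rep(1, 16)))
#' d1 <- velocityComponent(spectralGradient(f), 1)  # cos(x1)
#' @export
spectralGradient <- function(f) {
  stopifnot(is(f, "ScalarField"))
  grid <- f@grid
  fhat <- fftn(f@values)
  comps <- lapply(grid@kderiv, function(k) {
    ifftn_real(1i * k * fhat)
  })
  new("VelocityField", grid = grid, components = comps)
}

#' Spectral divergence of a velocity field
#'
#' \eqn{\nabla\cdot v = \sum_a \partial_a v_a}, each derivative taken
#' spectrally. Linear in v.
#'
#' @param v a [VelocityField-class].
#' @return a [ScalarField-class].
#' @export
spectralDivergence <- function(v) {
  stopifnot(is(v, "VelocityField"))
  grid <- v@grid
  acc <- array(0, dim = grid@dims)
  for (a in seq_along(v@components)) {
    acc <- acc + ifftn_real(1i * grid@kderiv[[a]] * fftn(v@components[[a]]))
  }
  scalarField(grid, acc)
}

#' Apply the Sobolev regularization operator
#'
#' Applies, componentwise in Fourier space, the differential operator A
#' whose quadratic form is the chosen Sobolev (semi)norm:
#' \code{"h1s"} gives \eqn{-\Delta}, \code{"h1"} gives \eqn{-\Delta + I},
#' and \code{"h2s"} gives \eqn{\Delta^2}. A is linear, self-adjoint, and
#' positive semi-definite (definite for \code{"h1"}).
#'
#' @param v a [VelocityField-class].
#' @param model "h1s", "h1" or "h2s".
#' @return a [VelocityField-class], \eqn{A v}.
#' @export
regularizationApply <- function(v, model = "h1s") {
  stopifnot(is(v, "VelocityField"))
  sym <- reg_symbol(v@grid, model)
  comps <- lapply(v@components, function(comp) {
    ifftn_real(sym * fftn(comp))
  })
  new("VelocityField", grid = v@grid, components = comps)
}

#' Invert the shifted Sobolev operator (spectral preconditioner)
#'
#' Solves \eqn{(\alpha A + s I) u = g} exactly in Fourier space, where A is
#' the regularization operator of the chosen model and \eqn{s \ge 0} is a
#' shift. This is the reduced-space Hessian preconditioner: the seminorm
#' operators (h1s, h2s) annihilate constants, so their inverse requires
#' \code{shift > 0}; the default is \code{1e-3 * alpha}.
#'
#' @param g a [VelocityField-class], the right-hand side.
#' @param model "h1s", "h1" or "h2s".
#' @param alpha positive weight on A.
#' @param shift nonnegative shift; must be positive for seminorm models.
#' @return a [VelocityField-class], \eqn{(\alpha A + s I)^{-1} g}.
#' @export
regularizationInverse <- function(g, model = "h1s", alpha = 1,
                                  shift = 1e-3 * alpha) {
  stopifnot(is(g, "VelocityField"))
  if (alpha <= 0) stop("alpha must be positive")
  if (shift < 0) stop("shift must be nonnegative")
  if (shift == 0 && model %in% c("h1s", "h2s")) {
    stop("seminorm operator is singular on constants; a positive shift is required")
  }
  sym <- alpha * reg_symbol(g@grid, model) + shift
  comps <- lapply(g@components, function(comp) {
    ifftn_real(fftn(comp) / sym)
  })
  new("VelocityField", grid = g@grid, components = comps)
}
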