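---
title: "Methods: stationary-velocity diffeomorphic registration in DiffeoFlow"
author: "DiffeoFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stationary-velocity diffeomorphic registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The registration problem

Given a template image $m_0(x)$ and a reference image $m_1(x)$ on a common
grid, deformable registration seeks a map $y(x)$ with
$m_0(y(x)) \approx m_1(x)$ that is a *diffeomorphism*: continuous,
one-to-one, with a smooth inverse. DiffeoFlow parameterizes the map by a
smooth, **stationary velocity field** $v(x)$ whose flow over the unit time
interval carries the template onto the reference. The velocity is found by
solving the PDE-constrained optimization problem

$$
\min_{v}\; \tfrac12 \int_\Omega \big(m(x,1) - m_1(x)\big)^2\,dx
\;+\; \tfrac{\alpha}{2}\,\langle A v, v\rangle
\;+\; \tfrac{\gamma}{2}\int_\Omega (\nabla\!\cdot v)^2\,dx
$$

subject to the transport (state) equation

$$
\partial_t m + v\cdot\nabla m = 0, \qquad m(x,0) = m_0(x),
\qquad t \in [0,1].
$$

The first term is the squared $L^2$ image distance at the flow endpoint.
The second is Sobolev regularization: $A$ is a differential operator whose
quadratic form is the chosen (semi)norm, and it is what makes the flow
smooth and the map diffeomorphic. The third term is a quadratic penalty on
the divergence of $v$ — a relaxation of a hard incompressibility
constraint; with weight $\gamma$ large, the flow becomes nearly
volume-preserving ($\det\nabla y \approx 1$).

The domain is fixed to the periodic box $[0, 2\pi)^d$, $d \in \{2,3\}$,
which is what makes exact FFT-based (spectral) differentiation available.
Images are placed on this grid regardless of their physical voxel spacing
(the spacing is carried through NIfTI headers but does not enter the
solve; anisotropic spacing is out of scope). Periodicity is an assumption:
images whose content touches the boundary will interact across the seam,
and users should pad such data before registration.

# Optimality system and reduced gradient

Introducing a Lagrange multiplier $\lambda(x,t)$ for the transport
constraint and eliminating the state gives the reduced gradient

$$
g(v) = \alpha A v \;-\; \gamma\,\nabla(\nabla\!\cdot v)
\;+\; \int_0^1 \lambda\,\nabla m \; dt ,
$$

where $\lambda$ solves the adjoint **continuity equation**

$$
-\partial_t \lambda - \nabla\!\cdot(v\,\lambda) = 0,
\qquad \lambda(x,1) = m_1(x) - m(x,1),
$$

integrated backward from the terminal mismatch. The sign convention makes
$g$ the gradient of the minimized objective, so $-g$ is a descent
direction; at $v = 0$ with $m_0 = m_1$ the gradient vanishes identically.

# Discretization

## Spectral operators

All spatial derivatives are diagonal in Fourier space. On an even grid the
first-derivative symbol $ik$ is set to zero at the Nyquist mode (the
standard convention for odd-order derivatives), while even-order symbols
($|k|^2$, $|k|^4$) retain it. The three regularization models are

| model | operator $A$ | symbol |
|-------|--------------|--------|
| `h1s` | $-\Delta$ per component | $|k|^2$ |
| `h1`  | $-\Delta + I$ | $|k|^2 + 1$ |
| `h2s` | $\Delta^2$ | $|k|^4$ |

All are self-adjoint and positive semi-definite (`h1` is definite). The
seminorms annihilate constant fields, so their inverse — used as the
Krylov preconditioner — is regularized by a positive shift $s$:
$(\alpha A + sI)^{-1}$ is an exact pointwise division in Fourier space.
The standalone inverse defaults to $s = 10^{-3}\alpha$ (just enough to fix
the constant mode); inside the solver the preconditioner shift defaults to
$1$, because the Gauss–Newton body term behaves like an $O(1)$ $L^2$ mass
term for intensity-normalized images, and a tiny shift would overamplify
the constant mode that $A$ annihilates. Transforms use R's complex FFT
with the real part taken after the inverse transform; for real fields this
is equivalent to a real-to-complex half-spectrum implementation.

## Semi-Lagrangian transport

The state equation is advanced by $n_t$ unconditionally stable
semi-Lagrangian steps: each step traces the characteristic backward from
every node with an RK2 (midpoint) rule,
$x^* = x - \delta t\, v(x - \tfrac{\delta t}{2} v(x))$, and evaluates the
previous frame at $x^*$ by interpolation. Because $v$ is stationary the
departure points are computed once per step size and reused.

Interpolation is periodic piecewise-cubic **spline** interpolation: a
uniform cubic B-spline kernel applied to coefficients obtained by an exact
spectral prefilter (division by the B-spline symbol
$(4 + 2\cos 2\pi k/n)/6$ per axis). This kernel is $C^2$ and fourth-order
accurate, and its smoothness matters beyond pointwise accuracy: the
finite-difference consistency of the adjoint gradient is limited by the
smoothness of the interpolant's derivative. With a merely $C^1$ kernel
(e.g. Catmull–Rom) the gradient-vs-objective agreement plateaus at
$O(h^2)$ — about $3\cdot10^{-3}$ relative on a $64^2$ grid, independent of
$n_t$ — while the spline brings the same test below $10^{-3}$ with an
order of magnitude to spare. A multilinear (order 1) fallback is available
and is the variant that satisfies a discrete maximum principle.

The adjoint continuity equation is solved backward by the matching
scheme: from node $x$ the characteristic is traced *forward* to
$x + \delta t\, v$ (RK2), the later frame is interpolated there, and the
result is scaled by $\exp(\delta t\, \nabla\!\cdot v)$ evaluated at the
characteristic midpoint — the midpoint-rule quadrature of the
compressibility source $\dot\lambda = -\lambda \nabla\!\cdot v$ along the
characteristic. The exponential midpoint form keeps the scheme second
order in time and conserves $\int\lambda\,dx$ (an exact invariant of the
continuity equation) to $\sim10^{-6}$ relative at $n_t = 16$; a first-order
multiplicative splitting $(1 \pm \delta t\,\nabla\!\cdot v)$ would cap the
observable convergence order at one and conserve mass only to $O(\delta t)$.

The gradient assembled from this adjoint is the *continuous* adjoint
discretized, not the exact discrete adjoint of the semi-Lagrangian scheme.
The gap between the two is second order in both $\delta t$ and (through
the spline) effectively $O(h^3)$ in space; the finite-difference gradient
test quantifies it (below $10^{-3}$ relative at the optimal step across
all models on $64^2$ with default $n_t = 8$).

## Gauss–Newton–Krylov solver

The outer iteration is a reduced-space Gauss–Newton method starting from
$v = 0$:

1. Solve the state forward, the adjoint backward; assemble $J(v)$ and $g(v)$.
2. Stop when $\|g\| \le \texttt{outerTol}\,\|g_0\|$ (plus a $10^{-14}$
   absolute floor so that identical images stop at iteration 0).
3. Solve $H p = -g$ by preconditioned conjugate gradients. The
   Gauss–Newton Hessian is applied matrix-free: the incremental state
   equation $\partial_t\tilde m + v\cdot\nabla\tilde m + w\cdot\nabla m = 0$,
   $\tilde m(0)=0$ (semi-Lagrangian step with trapezoidal source along the
   characteristic), the incremental adjoint with terminal value
   $-\tilde m(1)$, then
   $Hw = \alpha A w - \gamma\nabla(\nabla\!\cdot w) + \int_0^1
   \tilde\lambda \nabla m\, dt$. Dropping the second-order constraint
   terms makes $H$ positive semi-definite by construction, at the price of
   exact symmetry: the discretized matvec is symmetric only to
   discretization error (measured $\lesssim 10^{-3}$ relative for smooth
   probe directions on $16^2$). PCG truncates on detected nonpositive
   curvature and returns the current (or preconditioned steepest-descent)
   iterate.
4. Armijo backtracking from a unit step with $c_1 = 10^{-4}$.

Time quadrature of all body-force integrals is the trapezoidal rule over
the $n_t + 1$ frames, with $\nabla m$ per frame by spectral
differentiation. The distance and penalty integrals use the rectangle rule
$h^d \sum$, which is spectrally accurate for periodic integrands (doubling
the resolution of a band-limited integrand changes the value only at
rounding level).

## Defaults

| parameter | default | meaning |
|-----------|---------|---------|
| `regModel` | `"h1s"` | H1-seminorm regularization |
| `alpha` | $10^{-2}$ | regularization weight |
| `divGamma` | 0 | divergence penalty off |
| `nt` | 8 | time steps over $[0,1]$ |
| `interpOrder` | 3 | cubic spline interpolation |
| `outerTol` | $5\cdot10^{-2}$ | relative gradient reduction |
| `outerMaxit` | 50 | outer iteration cap |
| `krylovTol` | $10^{-1}$ | fixed PCG tolerance (no forcing sequence) |
| `krylovMaxit` | 50 | PCG iteration cap |
| `lsC1`, `lsMaxit` | $10^{-4}$, 20 | Armijo constant, halvings |
| `precondShift` | 1 | shift in $(\alpha A + sI)^{-1}$ |

Single-level solves only: no multi-resolution, no $\alpha$-continuation,
no inexact-Newton forcing. All arithmetic is double precision.

# Deformation maps and diagnostics

The deformation map is obtained by integrating the characteristics of the
stationary $v$ over $[0,1]$ with $n_t$ RK2 steps and is stored as an
*unwrapped displacement* relative to the identity, which keeps periodic
wrapping unambiguous. The package fixes the pullback convention: the
**forward** map satisfies (warped template) $=$ (transported template),
i.e. $m_0(y(x)) \approx m(x,1)$; for a constant velocity $(c, 0)$ the
forward map is $y(x) = x - (c, 0)$. The inverse map integrates the
opposite flow, and the two compose to the identity up to $O(h^2 +
\delta t^2)$ (measured $3\cdot10^{-5}$ max displacement on $32^2$ at
$n_t = 16$).

The diffeomorphism diagnostic is the Jacobian determinant
$\det(I + \nabla u)$ with the displacement gradient taken spectrally,
consistent with the rest of the code. Positivity everywhere is the
discrete check that the map is locally one-to-one; the identity map gives
exactly 1, and determinants are multiplicative under flow composition up
to discretization error.

# Synthetic problems and what passing tests mean

The generator builds reproducible ground-truth problems: a template of
seeded periodic Gaussian bumps (default 3; centers uniform, widths
0.4–0.9, amplitudes 0.6–1, normalized to $[0,1]$), a band-limited random
velocity (modes $|k_a| \le 4$, amplitudes $\propto (1+|k|^2)^{-1}$)
rescaled to a prescribed maximum speed, and a reference image produced by
high-accuracy transport ($n_t = 64$). At generation time the ground-truth
map is verified to have a positive Jacobian determinant (the velocity is
shrunk 20% at a time if not). The committed end-to-end fixture is seed 42
on $64^2$ with magnitude 0.3.

These fixtures emulate smooth, noise-free, mono-modal image pairs whose
deformation is exactly realizable by the model. They do **not** emulate
intensity noise, contrast differences between modalities, sharp edges or
fine texture, non-periodic anatomy, or deformations outside the
stationary-velocity class. Passing tests therefore demonstrate
correctness of the discretization and optimizer, not robustness on
clinical data.

Two measurement choices deserve note. First, temporal self-convergence of
the transport solvers is measured on a $128^2$ grid: the accumulated
spline-interpolation error is an $n_t$-independent floor, and on coarser
grids it masks the $O(\delta t^2)$ term over part of the range
$n_t \in \{4, 8, 16\}$; at $128^2$ the observed least-squares order is
$\approx 1.9$ for both solvers. Second, the finite-difference gradient
test probes along the normalized gradient direction: for a random
direction the pairing $\langle g, w\rangle$ can nearly cancel, making the
*relative* comparison ill-conditioned even when the gradient is correct.

# Parameter recovery and non-uniqueness

Recovering the *velocity* (rather than the mismatch) is only partially
possible: the objective constrains $v$ only where the image has gradient,
so any component of the ground-truth velocity supported in flat regions
is invisible and is suppressed by the regularizer. The recovery experiment
therefore uses a dense template (10 bumps), weak regularization
($\alpha = 10^{-3}$) and a tight outer tolerance ($10^{-2}$). Under these
conditions, ground-truth fields with max speed 0.2 are recovered with
cosine similarity 0.76–0.86 and relative $L^2$ error 0.51–0.68 across
seeds — strong correlation, with the residual dominated by the
unidentifiable null-space component (stationary-velocity
parameterizations of a given endpoint map are not unique). The mismatch
itself is removed to below 10% in every case.

# Degenerate inputs and edge conventions

* Constant images: normalization maps them to zero; registering identical
  images returns $v \equiv 0$, converged at iteration 0, with mismatch
  ratio 1 by convention.
* Seminorm inverse with zero shift is refused (singular on constants).
* Departure points are wrapped into $[0, 2\pi)$; a modulo result that
  rounds to exactly $2\pi$ is mapped back to 0.
* Non-square volumes are rejected at I/O (the periodic grid is square by
  construction); NaN voxels and 4D volumes are rejected with explicit
  errors.
* `dt * max|v|` exceeding the domain extent triggers a warning (the
  scheme remains stable but accuracy degrades).

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic 2D
problems: $8^2$–$16^2$ for oracle comparisons and operator algebra,
$32^2$ for transport and deformation diagnostics, $64^2$ for gradient
checks and the registration fixtures, $128^2$ for the temporal-order
measurement; 3D code paths are exercised at $16^3$ through I/O. The
count of unknowns of the discretized problem, $d \cdot N^d$, is what
connects these desk-scale runs to clinical ($3\cdot 256^3 \approx 50$
million) and extreme ($3\cdot 2048^3 \approx 25.8$ billion) resolutions,
which require the distributed-memory machinery that is out of scope here.

# Known limitations

* $L^2$ distance only; no cross-correlation or mutual information, so no
  multi-modal registration.
* Periodic boundary conditions; no affine pre-registration; no DICOM.
* Single-level optimization without continuation can stall on very large
  deformations (max speed well above 0.5 on $64^2$).
* The exact-incompressibility limit is approached only through the
  penalty weight $\gamma$, not enforced as a hard constraint.
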