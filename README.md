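# DiffeoFlow

Large-deformation diffeomorphic image registration for 2D and small 3D
images, written for people who want a transparent, desk-scale
implementation of the velocity-field optimal-control formulation: medical
image analysts studying the method itself, and developers who need a
reference against which to validate faster production code.

## The problem and the method

Registration of a template image $m_0$ to a reference $m_1$ is posed as
PDE-constrained optimization over a smooth **stationary velocity field**
$v(x)$:

$$
\min_v\; \tfrac12\|m(\cdot,1)-m_1\|_{L^2}^2
 + \tfrac{\alpha}{2}\langle Av,v\rangle
 + \tfrac{\gamma}{2}\|\nabla\!\cdot v\|_{L^2}^2
\quad\text{s.t.}\quad
\partial_t m + v\cdot\nabla m = 0,\; m(\cdot,0)=m_0 .
$$

The flow of $v$ over $t\in[0,1]$ generates the spatial map $y(x)$; Sobolev
regularization ($A$ = H1-seminorm, full H1, or H2-seminorm operator) keeps
the map a diffeomorphism, which is verified a posteriori by positivity of
$\det\nabla y$. The implementation uses:

* **semi-Lagrangian transport** (RK2 characteristic trace + periodic cubic
  spline interpolation) for the state and adjoint (continuity) equations —
  unconditionally stable in the step count;
* **FFT spectral differentiation** on the periodic domain $[0,2\pi)^d$ for
  all derivatives, regularization operators, and their exact inverses;
* an **adjoint-state reduced gradient** and a matrix-free
  **Gauss–Newton–Krylov** outer solver: PCG on the reduced Hessian,
  preconditioned by the inverse (shifted) regularization operator, with
  Armijo backtracking.

The methods vignette (`vignettes/diffeomorphic-registration.Rmd`) derives
the optimality system and documents every discretization choice, default,
and limitation.

## Worked example

Register a synthetic problem with known ground truth (seed 42, $64^2$
grid, a deformation with maximum speed 0.3):

```r
library(DiffeoFlow)

prob <- generateSyntheticProblem(seed = 42, dims = c(64, 64), magnitude = 0.3)
res  <- registerImages(prob@m0, prob@m1, registrationConfig(), verbose = TRUE)
#> it   0  J = 1.800557e-02  |g| = 1.415e-01
#> it   1  J = 2.338381e-03  |g| = 2.167e-02  step 1  krylov 4
#> it   2  J = 1.595369e-03  |g| = 3.286e-03  step 1  krylov 15
res
#> RegistrationResult: 3 outer iterations, converged = TRUE
#>   final/initial L2 mismatch: 0.02366
#>   min det(Jacobian) of forward map: 0.9014
```

Reading the output: the objective `J` (distance + regularization) drops
an order of magnitude in the first Gauss–Newton step and the gradient
norm `|g|` falls by the factor 20 required by the default stopping rule
within two steps, each accepting the full step after a short inner PCG
solve. The final $L^2$ mismatch is 2.4% of its initial value — 97.6% of
the image difference removed — and the smallest Jacobian determinant of
the recovered map is 0.90, comfortably positive, so the correspondence is
diffeomorphic. The warped template, residual, map, and determinant field
can be inspected via `warpImage(prob@m0, res@map)`,
`jacobianDeterminant(res@map)`, and written to NIfTI with `writeImage()`.

## Command line

A thin CLI wraps the same functions (flags override config-file values):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "diffeoflow.R", package = "DiffeoFlow"))')
Rscript $CLI synth    --seed 42 --dims 64 --magnitude 0.3 -x out/synth
Rscript $CLI register -mr out/synth/reference.nii.gz \
                      -mt out/synth/template.nii.gz \
                      -x out/reg -alpha 0.01 -regmodel h1s -nt 8
Rscript $CLI metrics  --result out/reg
```

`register` writes `velocity-field-x{1,2}.nii.gz`,
`deformation-map-x{1,2}.nii.gz`, `det-deformation-grad.nii.gz`,
`deformed-template.nii.gz`, `residual-after.nii.gz`, a `convergence.csv`
log (one row per outer iteration), and `metrics.txt`. Runs are
deterministic: a fixed seed and configuration reproduce every output file
byte for byte.

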