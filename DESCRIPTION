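Package: DiffeoFlow
Title: Diffeomorphic Image Registration with Stationary Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Large-deformation diffeomorphic image registration posed as
    PDE-constrained optimization over a smooth, stationary velocity field.
    Image intensities are transported by a semi-Lagrangian solver for the
    advection (state) equation; the reduced gradient is assembled from the
    adjoint (continuity) equation; Sobolev regularization and all spatial
    differentiation use FFT-based spectral operators on a periodic grid; the
    outer solver is a preconditioned Gauss-Newton-Krylov method. Includes
    deformation-map and Jacobian-determinant diagnostics, NIfTI input and
    output, a synthetic-problem generator with known ground truth, and a
    command-line interface for 2D and small 3D images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid-spectral.R'
    'transport.R'
    'objective.R'
    'optimize.R'
    'deformation.R'
    'io.R'
    'synthetic.R'
    'cli.R'
    'utils-internal.R'
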