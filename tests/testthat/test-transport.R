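test_that("departure points follow the RK2 characteristic trace", {
  g <- makeGrid(c(16, 16))
  v0 <- velocityField(g, list(matrix(0, 16, 16), matrix(0, 16, 16)))
  dep <- traceDeparturePoints(v0, dt = 0.2)
  x <- cbind(as.vector(outer(grid_axis(g), rep(1, 16))),
             as.vector(outer(rep(1, 16), grid_axis(g))))
  expect_lt(max(abs(dep@coords - x)), 1e-14)

  # constant velocity: RK2 is exact, x* = x - c*dt (mod 2*pi)
  vc <- velocityField(g, list(matrix(0.7, 16, 16), matrix(-0.3, 16, 16)))
  dep <- traceDeparturePoints(vc, dt = 0.25)
  expected <- cbind((x[, 1] - 0.7 * 0.25) %% (2 * pi),
                    (x[, 2] + 0.3 * 0.25) %% (2 * pi))
  expect_lt(max(abs(dep@coords - expected)), 1e-12)

  expect_error(traceDeparturePoints(vc, dt = -1), "positive")
  expect_warning(traceDeparturePoints(vc, dt = 20), "accuracy")
})

test_that("rigid-rotation departure points match a fine-step RK4 oracle", {
  n <- 32
  g <- makeGrid(c(n, n))
  x1 <- grid_axis(g)
  X1 <- outer(x1, rep(1, n))
  X2 <- outer(rep(1, n), x1)
  v <- velocityField(g, list(-(X2 - pi), X1 - pi))  # rotation about center
  dt <- 0.1
  dep <- traceDeparturePoints(v, dt)

  # oracle: 100-substep RK4 on the analytic rotation field
  x <- cbind(as.vector(X1), as.vector(X2))
  vf <- function(p) cbind(-(p[, 2] - pi), p[, 1] - pi)
  p <- x
  h <- -dt / 100
  for (i in 1:100) {
    k1 <- vf(p); k2 <- vf(p + h / 2 * k1)
    k3 <- vf(p + h / 2 * k2); k4 <- vf(p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  oracle <- p %% (2 * pi)
  # the sampled rotation field is non-periodic across the domain seam, so
  # compare away from it (the RK2 truncation error itself is O(dt^3))
  interior <- sqrt((x[, 1] - pi)^2 + (x[, 2] - pi)^2) < 2
  err <- sqrt(rowSums((dep@coords - oracle)^2))
  expect_lt(max(err[interior]), 2 * dt^3)
})

test_that("periodic interpolation is nodally exact, accurate, and linear", {
  g <- makeGrid(c(32, 32))
  x <- grid_axis(g)
  f <- scalarField(g, outer(sin(x), rep(1, 32)))
  v0 <- velocityField(g, list(matrix(0, 32, 32), matrix(0, 32, 32)))
  nodes <- traceDeparturePoints(v0, dt = 1)
  for (ord in c(1L, 3L)) {
    expect_lt(max(abs(fieldValues(periodicInterpolate(f, nodes, ord)) -
                      fieldValues(f))), 1e-13)
  }

  set.seed(9)
  pts <- matrix(stats::runif(200, 0, 2 * pi), ncol = 2)
  # constants are reproduced at arbitrary points
  expect_lt(max(abs(periodicInterpolate(scalarField(g, 2.5), pts, 3) - 2.5)),
            1e-12)
  # cubic accuracy against the analytic field
  expect_lt(max(abs(periodicInterpolate(f, pts, 3) - sin(pts[, 1]))), 1e-4)
  # linearity in the field values
  f2 <- bandlimited_field(g, 71, kmax = 4)
  lhs <- periodicInterpolate(scalarField(g, 2 * fieldValues(f) -
                                            3 * fieldValues(f2)), pts, 3)
  rhs <- 2 * periodicInterpolate(f, pts, 3) - 3 * periodicInterpolate(f2, pts, 3)
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  expect_error(periodicInterpolate(f, matrix(c(NaN, 1), 1, 2), 3), "finite")
  expect_error(periodicInterpolate(f, pts, 2L), "order")
})

test_that("state solver transports translations analytically", {
  g <- makeGrid(c(32, 32))
  x <- grid_axis(g)
  m0 <- scalarField(g, outer(sin(x), rep(1, 32)))
  # zero velocity: all frames identical to m0
  v0 <- velocityField(g, list(matrix(0, 32, 32), matrix(0, 32, 32)))
  tr0 <- solveState(m0, v0, nt = 4)
  for (k in 1:5) {
    expect_lt(max(abs(fieldValues(trajectoryFrame(tr0, k)) -
                      fieldValues(m0))), 1e-13)
  }
  # unit translation along x1: final frame is sin(x1 - 1)
  vc <- velocityField(g, list(matrix(1, 32, 32), matrix(0, 32, 32)))
  tr <- solveState(m0, vc, nt = 8)
  expect_length(tr@frames, 9L)
  expect_lt(max(abs(fieldValues(trajectoryFrame(tr, 9)) -
                    outer(sin(x - 1), rep(1, 32)))), 1e-3)
  # constants are preserved exactly under any velocity
  v <- rand_velocity(g, 81, mag = 0.4)
  trc <- solveState(scalarField(g, 0.8), v, nt = 8)
  expect_lt(max(abs(fieldValues(trajectoryFrame(trc, 9)) - 0.8)), 1e-12)
  expect_error(solveState(m0, rand_velocity(makeGrid(c(16, 16)), 1), 4),
               "grid")
})

test_that("order-1 state solve satisfies the discrete maximum principle", {
  g <- makeGrid(c(32, 32))
  m0 <- bandlimited_field(g, 91, kmax = 4)
  v <- rand_velocity(g, 92, mag = 0.5)
  tr <- solveState(m0, v, nt = 8, interpOrder = 1L)
  for (k in seq_along(tr@frames)) {
    expect_gte(min(fieldValues(trajectoryFrame(tr, k))),
               min(fieldValues(m0)) - 1e-12)
    expect_lte(max(fieldValues(trajectoryFrame(tr, k))),
               max(fieldValues(m0)) + 1e-12)
  }
})

test_that("adjoint solver translates backward and conserves mass", {
  g <- makeGrid(c(32, 32))
  x <- grid_axis(g)
  lam <- scalarField(g, outer(sin(x), rep(1, 32)))
  v0 <- velocityField(g, list(matrix(0, 32, 32), matrix(0, 32, 32)))
  ad0 <- solveAdjoint(lam, v0, nt = 4)
  for (k in 1:5) {
    expect_lt(max(abs(fieldValues(trajectoryFrame(ad0, k)) -
                      fieldValues(lam))), 1e-13)
  }
  # divergence-free constant v = (1, 0): frame at t=0 is sin(x1 + 1)
  vc <- velocityField(g, list(matrix(1, 32, 32), matrix(0, 32, 32)))
  ad <- solveAdjoint(lam, vc, nt = 8)
  expect_lt(max(abs(fieldValues(trajectoryFrame(ad, 1)) -
                    outer(sin(x + 1), rep(1, 32)))), 1e-3)
  # compressible velocity: integral of lambda conserved (continuity eq)
  v <- rand_velocity(g, 95, mag = 0.5)
  lamp <- scalarField(g, 1 + 0.5 * bandlimited_values(32, 96, 3, 1))
  adc <- solveAdjoint(lamp, v, nt = 16)
  hd <- prod(gridSpacing(g))
  m1 <- hd * sum(fieldValues(trajectoryFrame(adc, 17)))
  m0 <- hd * sum(fieldValues(trajectoryFrame(adc, 1)))
  expect_lt(abs(m0 - m1) / abs(m1), 1e-2)
})

test_that("state and adjoint solvers self-converge in the step count", {
  # measured against an nt = 256 reference of the same spatial scheme;
  # errors must decrease monotonically with nt
  g <- makeGrid(c(64, 64))
  v <- rand_velocity(g, 21, kmax = 3, mag = 0.5)
  m0 <- bandlimited_field(g, 23, kmax = 3)
  ref <- fieldValues(trajectoryFrame(solveState(m0, v, 256), 257))
  errs <- vapply(c(4L, 8L, 16L), function(nt) {
    max(abs(fieldValues(trajectoryFrame(solveState(m0, v, nt), nt + 1)) - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(log2(errs[1] / errs[2]), 1)

  lam <- scalarField(g, 1 + 0.5 * bandlimited_values(64, 24, 3, 1))
  refA <- fieldValues(trajectoryFrame(solveAdjoint(lam, v, 256), 1))
  errsA <- vapply(c(4L, 8L, 16L), function(nt) {
    max(abs(fieldValues(trajectoryFrame(solveAdjoint(lam, v, nt), 1)) - refA))
  }, numeric(1))
  expect_true(all(diff(errsA) < 0))
  expect_gt(log2(errsA[1] / errsA[2]), 1)
})
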