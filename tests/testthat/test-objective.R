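test_that("L2 distance has the closed form and matches direct summation", {
  g <- makeGrid(c(16, 16))
  f <- bandlimited_field(g, 11, kmax = 4)
  expect_identical(l2Distance(f, f), 0)
  # constant offset c: (1/2) c^2 (2*pi)^2
  c0 <- 0.37
  f2 <- scalarField(g, fieldValues(f) + c0)
  expect_lt(abs(l2Distance(f2, f) - 0.5 * c0^2 * (2 * pi)^2), 1e-12)
  expect_equal(l2Distance(f2, f), l2Distance(f, f2))
  # direct-summation oracle on 8^2
  g8 <- makeGrid(c(8, 8))
  a <- bandlimited_field(g8, 12, kmax = 3)
  b <- bandlimited_field(g8, 13, kmax = 3)
  acc <- 0
  for (i in 1:8) for (j in 1:8) {
    acc <- acc + (fieldValues(a)[i, j] - fieldValues(b)[i, j])^2
  }
  oracle <- 0.5 * (2 * pi / 8)^2 * acc
  expect_lt(abs(l2Distance(a, b) - oracle), 1e-12)
  expect_error(l2Distance(a, f), "grid")
})

test_that("regularization value has the closed form for a sine velocity", {
  g <- makeGrid(c(16, 16))
  cfg <- registrationConfig(regModel = "h1s", alpha = 0.25)
  vc <- velocityField(g, list(matrix(1, 16, 16), matrix(2, 16, 16)))
  expect_lt(regularizationValue(vc, cfg), 1e-12)
  # v = (sin(x1), 0): value = alpha (2*pi)^2 / 4
  x <- grid_axis(g)
  vs <- velocityField(g, list(outer(sin(x), rep(1, 16)), matrix(0, 16, 16)))
  expect_lt(abs(regularizationValue(vs, cfg) - 0.25 * (2 * pi)^2 / 4), 1e-10)
  # quadrature of |grad v|^2 via the DFT-summation oracle
  g8 <- makeGrid(c(8, 8))
  v <- rand_velocity(g8, 14, kmax = 3, mag = 1)
  acc <- 0
  for (a in 1:2) for (b in 1:2) {
    acc <- acc + sum(dft_gradient_oracle(
      fieldValues(velocityComponent(v, a)), b)^2)
  }
  oracle <- 0.5 * 0.25 * (2 * pi / 8)^2 * acc
  expect_lt(abs(regularizationValue(v, registrationConfig(alpha = 0.25)) -
                oracle), 1e-8)
})

test_that("divergence penalty vanishes for curl fields and matches the oracle", {
  g <- makeGrid(c(16, 16))
  v <- rand_velocity(g, 15, kmax = 3, mag = 1)
  expect_identical(divergencePenalty(v, 0), 0)
  # curl-type field (-d2 psi, d1 psi), psi = sin(x1) sin(x2): divergence-free
  x <- grid_axis(g)
  vcurl <- velocityField(g, list(-outer(sin(x), cos(x)),
                                 outer(cos(x), sin(x))))
  expect_lt(divergencePenalty(vcurl, 1), 1e-10)
  # direct sum on the spectral divergence
  q <- fieldValues(spectralDivergence(v))
  oracle <- 0.5 * (2 * pi / 16)^2 * sum(q^2)
  expect_lt(abs(divergencePenalty(v, 1) - oracle), 1e-10)
  expect_error(divergencePenalty(v, -1), "nonnegative")
})

test_that("objective assembles and decomposes into its three terms", {
  g <- makeGrid(c(16, 16))
  m0 <- bandlimited_field(g, 16, kmax = 3)
  v0 <- velocityField(g, list(matrix(0, 16, 16), matrix(0, 16, 16)))
  cfg <- registrationConfig(divGamma = 0.5)
  rep0 <- evaluateObjective(v0, m0, m0, cfg)
  expect_lt(rep0@total, 1e-20)
  # v = 0, different images: total is the plain L2 distance
  m1 <- bandlimited_field(g, 17, kmax = 3)
  rep1 <- evaluateObjective(v0, m0, m1, cfg)
  expect_equal(rep1@total, l2Distance(m0, m1))
  # term-wise decomposition with transport
  v <- rand_velocity(g, 18, mag = 0.3)
  rep2 <- evaluateObjective(v, m0, m1, cfg)
  tr <- solveState(m0, v, cfg@nt, cfg@interpOrder)
  dist <- l2Distance(trajectoryFrame(tr, length(tr@frames)), m1)
  expect_lt(abs(rep2@total - (dist + regularizationValue(v, cfg) +
                              divergencePenalty(v, cfg@divGamma))), 1e-12)
  expect_equal(rep2@distance, dist)
  expect_gte(rep2@regularization, 0)
  expect_gte(rep2@divPenalty, 0)
})

test_that("distance and penalty quadratures are resolution-independent", {
  # band-limited integrands: doubling the grid changes values only at
  # rounding level (spectral accuracy of the rectangle rule). The same
  # analytic function is sampled at both resolutions.
  fun <- function(n) {
    x <- (seq_len(n) - 1) * 2 * pi / n
    outer(sin(3 * x), rep(1, n)) + 0.5 * outer(rep(1, n), cos(2 * x)) +
      0.3 * outer(sin(x), sin(4 * x))
  }
  vals32 <- fun(32)
  vals64 <- fun(64)
  g32 <- makeGrid(c(32, 32))
  g64 <- makeGrid(c(64, 64))
  d32 <- l2Distance(scalarField(g32, vals32), scalarField(g32, 0))
  d64 <- l2Distance(scalarField(g64, vals64), scalarField(g64, 0))
  expect_lt(abs(d32 - d64) / d64, 1e-6)
  v32 <- velocityField(g32, list(vals32, -vals32))
  v64 <- velocityField(g64, list(vals64, -vals64))
  p32 <- divergencePenalty(v32, 1)
  p64 <- divergencePenalty(v64, 1)
  expect_lt(abs(p32 - p64) / p64, 1e-6)
})

test_that("reduced gradient vanishes at the trivial optimum and is exact for constant templates", {
  g <- makeGrid(c(32, 32))
  m0 <- bandlimited_field(g, 22, kmax = 3)
  v0 <- velocityField(g, list(matrix(0, 32, 32), matrix(0, 32, 32)))
  cfg <- registrationConfig(divGamma = 0.5)
  g0 <- reducedGradient(v0, m0, m0, cfg)
  expect_lt(vf_norm(g0), 1e-13)
  # constant template: body force vanishes, gradient is alpha A v + gamma term
  mc <- scalarField(g, 0.5)
  v <- rand_velocity(g, 23, mag = 0.4)
  gr <- reducedGradient(v, mc, mc, cfg)
  av <- regularizationApply(v, cfg@regModel)
  gq <- spectralGradient(spectralDivergence(v))
  exact <- vf_lincomb(cfg@alpha, av, -cfg@divGamma, gq)
  expect_lt(vf_maxabs_diff(gr, exact), 1e-10)
})

test_that("reduced gradient passes a finite-difference directional check", {
  # two spot checks at 32^2 (the full ten-configuration sweep at 64^2 runs
  # with the acceptance suite)
  for (case in list(list(seed = 3, model = "h1s", gamma = 0),
                    list(seed = 4, model = "h2s", gamma = 1))) {
    g <- makeGrid(c(32, 32))
    prob <- generateSyntheticProblem(case$seed, c(32, 32), magnitude = 0.25)
    cfg <- registrationConfig(regModel = case$model, divGamma = case$gamma)
    v <- rand_velocity(g, case$seed + 55, mag = 0.15)
    gr <- reducedGradient(v, prob@m0, prob@m1, cfg)
    w <- vf_lincomb(1 / vf_norm(gr), gr, 0, gr)
    gw <- vf_inner(gr, w)
    J <- function(vv) evaluateObjective(vv, prob@m0, prob@m1, cfg)@total
    rel <- min(vapply(10^-(2:6), function(h) {
      fd <- (J(vf_lincomb(1, v, h, w)) - J(vf_lincomb(1, v, -h, w))) / (2 * h)
      abs(fd - gw) / max(abs(fd), abs(gw))
    }, numeric(1)))
    expect_lt(rel, 5e-3)
  }
})
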