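# Gradient schemes, standard-model kernels, voxel simulation and noise
# contracts.

test_that("the default protocol yields 6 shells of 70 directions plus 30 b=0", {
  sch <- protocolScheme()
  expect_length(bvalues(sch), 450L)
  expect_identical(nShells(sch), 6L)
  tab <- shellTable(sch)
  expect_equal(tab$b, c(900, 1600, 2500, 3600, 4900, 6400))
  expect_true(all(tab$n == 70L))
  expect_length(sch@b0Index, 30L)
  expect_warning(makeScheme(bvalues = 1000, dirsPerShell = 1, nB0 = 0,
                            seed = 1), "fewer than 6")
})

test_that("optimized direction sets beat uniform random sets in minimum angle", {
  sch <- protocolScheme()
  ours <- minAngle(directions(sch)[sch@shellIndex[[1]], ])
  set.seed(17)
  beaten <- replicate(50, {
    m <- matrix(rnorm(210), 70, 3)
    minAngle(m / sqrt(rowSums(m^2))) < ours
  })
  expect_gte(mean(beaten), 0.95)
})

test_that("the standard-model response obeys its limiting cases", {
  k <- stmKernel(f = 0.37, Di = 2.4, De = 1.9, Dr = 0.6)
  expect_equal(stmSignal(k, 0, c(-1, 0, 0.5, 1)), rep(1, 4))
  # pure stick perpendicular to the gradient: no attenuation at any b
  stick <- stmKernel(f = 1, Di = 2.0, De = 0, Dr = 0)
  expect_equal(stmSignal(stick, c(900, 6400), 0), c(1, 1))
  expect_error(stmKernel(f = 1.2), "f must lie")
  expect_error(stmKernel(De = 0.5, Dr = 0.9), "De must be >=")
})

test_that("zonal projections match independent high-order quadrature", {
  # isotropic kernel: no angular contrast above l = 0
  iso <- stmKernel(f = 0, De = 1.5, Dr = 1.5)
  hbar <- kernelToZonal(iso, c(900, 6400), 8)
  expect_lt(max(abs(hbar[, -1])), 1e-10)
  # b -> 0: flat signal, l = 0 coefficient 2 sqrt(pi) * mean
  h0 <- kernelToZonal(stmKernel(), 1e-9, 8)
  expect_equal(h0[1, 1], 2 * sqrt(pi), tolerance = 1e-8)
  expect_lt(max(abs(h0[1, -1])), 1e-8)

  # stick kernel at b = 6400, Di = 2: against a composite 10^4-point
  # Gauss-Legendre rule (250 panels x 40 nodes) with Legendre polynomials
  # from pracma (independent code path)
  stick <- stmKernel(f = 1, Di = 2.0, De = 0, Dr = 0)
  got <- kernelToZonal(stick, 6400, 8)
  base <- pracma::gaussLegendre(40, 0, 1)
  edges <- seq(-1, 1, length.out = 251)
  x <- as.numeric(outer(base$x * diff(edges)[1], rep(1, 250)) +
                    rep(edges[-251], each = 40))
  w <- rep(base$w * diff(edges)[1], 250)
  H <- exp(-6400 * 2.0 * 1e-3 * x^2)
  for (j in seq_along(c(0, 2, 4, 6, 8))) {
    l <- c(0, 2, 4, 6, 8)[j]
    Pl <- if (l == 0) rep(1, length(x)) else pracma::legendre(l, x)[1, ]
    ref <- 2 * pi * sqrt((2 * l + 1) / (4 * pi)) * sum(w * H * Pl)
    expect_equal(unname(got[1, j]), ref, tolerance = 1e-8)
  }
  # closed form for l = 0: pi/sqrt(a) * erf(sqrt(a)) / sqrt(pi) * 2sqrt(pi)...
  a <- 6400 * 2.0 * 1e-3
  closed <- 2 * pi * sqrt(1 / (4 * pi)) * sqrt(pi / a) * pracma::erf(sqrt(a))
  expect_equal(unname(got[1, 1]), closed, tolerance = 1e-10)
})

test_that("equal-kernel configurations always reduce to a single convolution", {
  sch <- protocolScheme()
  # two equal kernels at 90 degrees, noise-free
  cfg <- fibreConfig(stmKernel(), rbind(c(0, 0, 1), c(1, 0, 0)),
                     weights = c(0.5, 0.5))
  y <- simulateVoxel(cfg, sch)
  expect_equal(powerRatio(shardDecompose(fitShellSH(y, sch, 8), 8)), 100,
               tolerance = 1e-10)

  # property: arbitrary geometry and weights, random equal kernel, 100 draws
  shellB <- shellTable(sch)$b
  set.seed(18)
  for (i in 1:100) {
    k <- randomKernel()
    n <- sample(1:3, 1)
    hbar <- kernelToZonal(k, shellB, 8)
    coef <- 0
    for (j in seq_len(n))
      coef <- coef + runif(1, 0.2, 2) *
        convolveSH(hbar, shBasis(rbind(randomUnitVector()), 8)[1, ])
    expect_equal(powerRatio(shardDecompose(coef, 8)), 100,
                 tolerance = 1e-10)
  }
})

test_that("kernel differences in a crossing create a genuine second component", {
  sch <- protocolScheme()
  kA <- stmKernel(f = 0.35)
  kB <- stmKernel(f = 0.65)
  cfg <- fibreConfig(list(kA, kB), rbind(c(0, 0, 1), c(1, 0, 0)),
                     weights = c(0.5, 0.5))
  y <- simulateVoxel(cfg, sch)
  dec <- shardDecompose(fitShellSH(y, sch, 8), 8)
  s <- pooledSigma(dec)
  expect_gt(s[2] / s[1], 1e-8)

  # oracle: the same voxel assembled directly as a sum of outer products
  shellB <- shellTable(sch)$b
  z <- shBasis(rbind(c(0, 0, 1)), 8)[1, ]
  x <- shBasis(rbind(c(1, 0, 0)), 8)[1, ]
  coef <- analyticCoefficients(list(kA, kB), list(0.5 * z, 0.5 * x),
                               shellB, 8)
  decOracle <- shardDecompose(coef, 8)
  expect_equal(s, pooledSigma(decOracle), tolerance = 1e-9)
  # and the second-order matrix genuinely has rank 2
  expect_equal(qr(buildShardMatrices(coef, 8)$S2, tol = 1e-9)$rank, 2L)
})

test_that("gaussian noise propagates to rank-1 residuals with the leverage deflation", {
  sch <- protocolScheme()
  design <- protocolDesign()
  cfg <- fibreConfig(stmKernel(), c(0, 0, 1), dispersion = 0.01)
  clean <- simulateVoxel(cfg, sch)
  snr <- 50
  h <- leverageFactor(6, 8, 70)@h
  n <- length(bvalues(sch))
  set.seed(19)
  mse <- vapply(seq_len(10000), function(i) {
    y <- clean + rnorm(n, 0, 1 / snr)
    dec <- shardDecompose(fitShellSH(y, NULL, 8, design = design), 8)
    fit <- rank1Reconstruct(dec, y, NULL, design = design)
    mean(fit$resid^2)
  }, numeric(1))
  expect_equal(mean(mse), (1 - h) / snr^2, tolerance = 0.02)
})

test_that("rician noise at SNR >= 30 barely shifts the mean signal", {
  sch <- protocolScheme()
  cfg <- fibreConfig(stmKernel(), c(0, 0, 1), dispersion = 0.01)
  nRep <- 400
  mg <- mr <- 0
  for (i in seq_len(nRep)) {
    mg <- mg + simulateVoxel(cfg, sch, snr = 30, noise = "gaussian",
                             seed = 1000 + i)
    mr <- mr + simulateVoxel(cfg, sch, snr = 30, noise = "rician",
                             seed = 5000 + i)
  }
  # mean over measurements of the mean-signal difference, relative to b0 = 1
  expect_lt(mean(abs(mr - mg) / nRep), 0.02)
})

test_that("dense-ODF signals show small truncation error that grows with b", {
  sch <- protocolScheme()
  design <- protocolDesign()
  cfg <- fibreConfig(stmKernel(), c(0, 0, 1))
  y <- simulateVoxel(cfg, sch, odf = "dense")
  coef <- fitShellSH(y, NULL, 8, design = design)
  relErr <- vapply(1:6, function(b) {
    idx <- sch@shellIndex[[b]]
    yhat <- design$B[[b]] %*% coef[b, ]
    sqrt(mean((y[idx] - yhat)^2)) / sqrt(mean(y[idx]^2))
  }, numeric(1))
  expect_lt(relErr[1], 1e-3)       # b = 900: nearly band-limited
  # b = 6400: a coherent (undispersed) stick carries ~10% relative power
  # beyond lmax = 8; still a small fraction of the signal
  expect_lt(relErr[6], 0.15)
  expect_gt(relErr[6], relErr[1])  # truncation error grows with b
})

test_that("a small power surface has the expected structure", {
  surf <- powerSurface(param = "f", deltas = c(0, 0.6), snrs = c(30, 120),
                       nVoxels = 12, nPerm = 99, seed = 5)
  expect_s3_class(surf, "powerSurface")
  expect_equal(nrow(surf), 4L)
  # nested significance levels: stricter alpha never rejects more
  expect_true(all(surf$rate_0.001 <= surf$rate_0.05))
  # strong difference at high SNR is detected
  expect_gt(surf$rate_0.05[surf$delta == 0.6 & surf$snr == 120], 0.5)
  expect_true(is.list(attr(surf, "contours")))
})
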