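# Per-order matrices, SVD decomposition, pooled effect sizes and the rank-1
# reconstruction.

test_that("per-order matrices have the shell-by-coefficient layout", {
  set.seed(10)
  coef <- matrix(rnorm(6 * shNCoef(8)), 6)
  S <- buildShardMatrices(coef, 8)
  expect_named(S, c("S0", "S2", "S4", "S6", "S8"))
  expect_equal(dim(S$S0), c(6L, 1L))
  expect_equal(dim(S$S2), c(6L, 5L))
  expect_equal(dim(S$S8), c(6L, 17L))
  expect_equal(qr(S$S0)$rank, 1L)  # single column: always rank 1
  expect_error(buildShardMatrices(coef[, 1:40]), "lmax")

  # single-convolution coefficients factor as outer products h_l p_l'
  k <- randomKernel()
  p <- randomODF(8)
  hbar <- kernelToZonal(k, c(900, 1600, 2500, 3600, 4900, 6400), 8)
  S1 <- buildShardMatrices(convolveSH(hbar, p), 8)
  lvals <- c(0, 2, 4, 6, 8)
  for (j in seq_along(lvals)) {
    l <- lvals[j]
    cols <- (l * (l + 1) / 2 - l + 1):(l * (l + 1) / 2 + l + 1)
    hl <- sqrt(4 * pi / (2 * l + 1)) * hbar[, j]
    expect_equal(S1[[j]], hl %o% p[cols], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("noise-free single convolution is exactly rank 1 and recovers kernel and ODF", {
  set.seed(11)
  shellB <- c(900, 1600, 2500, 3600, 4900, 6400)
  for (rep in 1:5) {
    k <- randomKernel()
    p <- randomODF(8)
    hbar <- kernelToZonal(k, shellB, 8)
    dec <- shardDecompose(convolveSH(hbar, p), 8)
    s <- pooledSigma(dec)
    expect_lt(max(s[-1]) / s[1], 1e-10)
    expect_equal(powerRatio(dec), 100, tolerance = 1e-10)

    # leading singular vectors recover h_l and p_l up to scale and sign
    lvals <- c(0, 2, 4, 6, 8)
    for (j in seq_along(lvals)) {
      l <- lvals[j]
      hl <- sqrt(4 * pi / (2 * l + 1)) * hbar[, j]
      u1 <- dec@u[[j]][, 1]
      cor1 <- sum(u1 * hl) / sqrt(sum(hl^2))
      expect_lt(abs(abs(cor1) - 1), 1e-8)
      cols <- (l * (l + 1) / 2 - l + 1):(l * (l + 1) / 2 + l + 1)
      pl <- p[cols]
      v1 <- dec@v[[j]][, 1]
      cor2 <- sum(v1 * pl) / sqrt(sum(pl^2))
      expect_lt(abs(abs(cor2) - 1), 1e-8)
    }
  }
})

test_that("identical kernels or identical ODFs up to scale reduce to rank 1", {
  set.seed(12)
  shellB <- c(900, 1600, 2500, 3600, 4900, 6400)
  k <- randomKernel()
  hbar <- kernelToZonal(k, shellB, 8)
  # same kernel scaled differently, two distinct ODFs
  coef <- convolveSH(0.7 * hbar, randomODF(8)) +
    convolveSH(0.3 * hbar, randomODF(8))
  expect_equal(powerRatio(shardDecompose(coef, 8)), 100, tolerance = 1e-10)

  # two distinct kernels sharing one ODF up to scale
  k2 <- randomKernel()
  p <- randomODF(8)
  coef2 <- convolveSH(kernelToZonal(k, shellB, 8), 0.4 * p) +
    convolveSH(kernelToZonal(k2, shellB, 8), 1.7 * p)
  expect_equal(powerRatio(shardDecompose(coef2, 8)), 100, tolerance = 1e-10)
})

test_that("distinct kernels in general position raise the rank as min(n, k, 2l+1)", {
  set.seed(13)
  shellB <- c(900, 1600, 2500, 3600, 4900, 6400)
  for (n in 2:3) {
    kernels <- replicate(n, randomKernel())
    odfs <- replicate(n, randomODF(8), simplify = FALSE)
    coef <- analyticCoefficients(kernels, odfs, shellB, 8)
    S <- buildShardMatrices(coef, 8)
    dec <- shardDecompose(S, 8)
    lvals <- c(0, 2, 4, 6, 8)
    for (j in seq_along(lvals)) {
      expected <- min(n, 6, 2 * lvals[j] + 1)
      # brute-force rank oracle on the assembled matrix
      expect_equal(qr(S[[j]], tol = 1e-10)$rank, expected)
      sv <- dec@sigmaL[[j]]
      expect_gt(sv[expected] / sv[1], 1e-9)
      if (expected < length(sv)) expect_lt(sv[expected + 1] / sv[1], 1e-10)
    }
  }
})

test_that("pooled energy equals the total Frobenius norm and is rotation invariant", {
  set.seed(14)
  coef <- matrix(rnorm(6 * shNCoef(8)), 6)
  S <- buildShardMatrices(coef, 8)
  dec <- shardDecompose(S, 8)
  totF <- sum(vapply(S, function(m) sum(m^2), numeric(1)))
  expect_equal(sum(pooledSigma(dec)^2), totF, tolerance = 1e-10)

  # rotating directions and fibre geometry together leaves sigma unchanged
  sch <- protocolScheme()
  axis <- c(0, 0, 1); axis2 <- c(1, 0, 0)
  cfg <- fibreConfig(list(stmKernel(), stmKernel(f = 0.8)),
                     rbind(axis, axis2), weights = c(0.5, 0.5))
  y <- simulateVoxel(cfg, sch)
  s0 <- pooledSigma(shardDecompose(fitShellSH(y, sch, 8), 8))

  theta <- 0.83
  Rz <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  Ry <- rbind(c(cos(0.4), 0, sin(0.4)), c(0, 1, 0), c(-sin(0.4), 0, cos(0.4)))
  Rot <- Ry %*% Rz
  sch2 <- gradientScheme(bvalues(sch), directions(sch) %*% t(Rot))
  cfg2 <- fibreConfig(list(stmKernel(), stmKernel(f = 0.8)),
                      rbind(as.numeric(Rot %*% axis), as.numeric(Rot %*% axis2)),
                      weights = c(0.5, 0.5))
  y2 <- simulateVoxel(cfg2, sch2)
  s2 <- pooledSigma(shardDecompose(fitShellSH(y2, sch2, 8), 8))
  expect_equal(s2, s0, tolerance = 1e-6)
})

test_that("degenerate all-zero voxel gets R = 100 with a flag", {
  dec <- shardDecompose(matrix(0, 6, shNCoef(8)), 8)
  expect_equal(powerRatio(dec), 100)
  expect_true(dec@degenerate)
})

test_that("rank-1 reconstruction is exact for rank-1 voxels and idempotent", {
  set.seed(15)
  sch <- protocolScheme()
  design <- protocolDesign()
  cfg <- fibreConfig(randomKernel(), randomUnitVector())
  y <- simulateVoxel(cfg, sch)
  dec <- shardDecompose(fitShellSH(y, sch, 8), 8)
  fit <- rank1Reconstruct(dec, y, sch, design = design)
  expect_lt(max(abs(fit$resid)), 1e-9)

  # idempotence on a noisy voxel: truncating the truncation changes nothing
  yn <- y + rnorm(length(y), 0, 0.02)
  decN <- shardDecompose(fitShellSH(yn, sch, 8), 8)
  fitN <- rank1Reconstruct(decN, yn, sch, design = design)
  y2 <- yn
  y2[fitN$dwiIndex] <- fitN$yhat
  dec2 <- shardDecompose(fitShellSH(y2, sch, 8), 8)
  fit2 <- rank1Reconstruct(dec2, y2, sch, design = design)
  expect_lt(max(abs(fit2$yhat - fitN$yhat)), 1e-9)
  expect_lt(max(abs(fit2$resid)), 1e-9)
})

test_that("scheme and decomposition mismatches are rejected", {
  sch <- protocolScheme()
  y <- simulateVoxel(fibreConfig(stmKernel(), c(0, 0, 1)), sch)
  dec <- shardDecompose(fitShellSH(y, sch, 8), 8)
  expect_error(rank1Reconstruct(dec, y, sch, design = protocolDesign(4L)),
               "lmax")
  sch3 <- makeScheme(bvalues = c(1000, 2000, 3000), seed = 3)
  expect_error(rank1Reconstruct(dec, y[1:240], sch3), "shell count")
})
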