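# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env()

# the 6-shell, 70-direction, 30 b=0 protocol
protocolScheme <- function() {
  if (is.null(.fx$sch)) .fx$sch <- makeScheme(seed = 1)
  .fx$sch
}

protocolDesign <- function(lmax = 8L) {
  key <- paste0("design", lmax)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- shardvox:::schemeDesign(protocolScheme(), lmax)
  .fx[[key]]
}

# product quadrature grid (Gauss-Legendre x uniform phi), built with pracma
# directly so oracle integrals do not share code with the package internals
oracleGrid <- function(nTheta = 64L, nPhi = 128L) {
  key <- sprintf("grid%d_%d", nTheta, nPhi)
  if (is.null(.fx[[key]])) {
    gl <- pracma::gaussLegendre(nTheta, -1, 1)
    phi <- 2 * pi * (seq_len(nPhi) - 1) / nPhi
    ct <- rep(gl$x, times = nPhi)
    st <- sqrt(pmax(1 - ct^2, 0))
    ph <- rep(phi, each = nTheta)
    .fx[[key]] <- list(
      points = cbind(st * cos(ph), st * sin(ph), ct),
      weights = rep(gl$w, times = nPhi) * (2 * pi / nPhi))
  }
  .fx[[key]]
}

randomUnitVector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

randomKernel <- function() {
  D <- sort(runif(2, 0.2, 3))
  stmKernel(f = runif(1, 0.1, 0.9), Di = runif(1, 1, 3),
            De = D[2], Dr = D[1])
}

randomODF <- function(lmax = 8L) rnorm(shNCoef(lmax))

# Noise-free per-shell coefficients of a multi-kernel configuration built
# directly as a sum of outer products sum_i h_{l,i} p_{l,i}' (the generalized
# multi-convolution forward model) -- used as an independent construction
# oracle against the simulate + fit pipeline.
analyticCoefficients <- function(kernels, odfs, shellB, lmax = 8L) {
  coef <- 0
  for (i in seq_along(kernels))
    coef <- coef + convolveSH(kernelToZonal(kernels[[i]], shellB, lmax),
                              odfs[[i]])
  coef
}

# Type-I calibration run under the rank-1 null (single dispersed fascicle,
# Gaussian noise at SNR 30): memoized because two suites inspect it.
nullCalibration <- function(nVoxels = 500L, nPerm = 999L, snr = 30,
                            seed = 20L) {
  key <- sprintf("null_%d_%d_%g_%d", nVoxels, nPerm, snr, seed)
  if (is.null(.fx[[key]])) {
    sch <- protocolScheme()
    design <- protocolDesign()
    cfg <- fibreConfig(stmKernel(), c(0, 0, 1), dispersion = 0.01)
    clean <- simulateVoxel(cfg, sch)
    n <- length(bvalues(sch))
    p2 <- numeric(nVoxels)
    discoveries <- NA
    withr::with_seed(seed, {
      for (v in seq_len(nVoxels)) {
        y <- clean + rnorm(n, 0, 1 / snr)
        res <- shardvox:::testVoxel(y, design, nPerm = nPerm,
                                    seed = sample.int(2^30, 1),
                                    components = 2L)
        p2[v] <- res$p[1L]
      }
    })
    .fx[[key]] <- list(p2 = p2, fdrMask = fdrCorrect(p2, 0.05))
  }
  .fx[[key]]
}
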