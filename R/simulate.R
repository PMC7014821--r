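# Synthetic multi-shell dMRI: gradient schemes, standard-model kernels,
# multi-fascicle voxel signals and the detectability power surface.

goldenAngle <- pi * (3 - sqrt(5))

# Spherical Fibonacci covering: n near-uniform points on the full sphere.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- goldenAngle * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Electrostatic-repulsion optimization of n gradient directions with
# antipodal symmetry (each point repels both the others and their
# antipodes), started from a Fibonacci hemisphere covering.  Deterministic.
repulsionDirections <- function(n, iterations = 300L, step = 0.02) {
  x <- fibonacciSphere(2L * n)
  x <- x[x[, 3] >= 0, , drop = FALSE][seq_len(n), , drop = FALSE]
  for (it in seq_len(iterations)) {
    G <- tcrossprod(x)                        # cos angles
    F <- matrix(0, n, 3)
    for (s in c(1, -1)) {
      # squared chord distance to (s * x_j): 2 - 2 s G
      d2 <- pmax(2 - 2 * s * G, 1e-12)
      w <- 1 / (d2 * sqrt(d2))                # Coulomb: (xi - s xj)/|.|^3
      diag(w) <- 0
      F <- F + (rowSums(w) * x) - s * (w %*% x)
    }
    # project force onto the tangent plane, take a normalized step
    F <- F - rowSums(F * x) * x
    mx <- max(sqrt(rowSums(F^2)))
    if (mx < 1e-12) break
    x <- x + step * F / mx
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

# Uniform random rotation matrix (quaternion method).
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Construct a gradient scheme from raw b-values and directions
#'
#' Groups b-values into shells: values within \code{tolerance} of each other
#' (greedy grouping on the sorted values) form one shell at their mean
#' b-value; values below \code{tolerance} are b=0 volumes.  Directions of
#' diffusion-weighted measurements are renormalized to unit length.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param dirs numeric matrix (n x 3) of gradient directions (b=0 rows may be
#'   zero vectors).
#' @param tolerance shell grouping tolerance in s/mm^2 (default 50).
#' @return a [GradientScheme-class].
#' @export
gradientScheme <- function(bvals, dirs, tolerance = 50) {
  dirs <- rbind(dirs)
  if (length(bvals) != nrow(dirs))
    stop(sprintf("%d b-values but %d direction rows", length(bvals), nrow(dirs)))
  b0 <- which(bvals < tolerance)
  dw <- which(bvals >= tolerance)
  if (length(dw)) {
    nrm <- sqrt(rowSums(dirs[dw, , drop = FALSE]^2))
    if (any(nrm < 1e-12))
      stop("zero-length gradient direction at b > 0 (measurement ",
           paste(dw[nrm < 1e-12], collapse = ", "), "): cannot normalize")
    dirs[dw, ] <- dirs[dw, , drop = FALSE] / nrm
  }
  # greedy grouping of sorted diffusion-weighted b-values
  shellIndex <- list(); shellB <- numeric()
  if (length(dw)) {
    o <- dw[order(bvals[dw])]
    cur <- o[1L]
    for (i in o[-1L]) {
      if (bvals[i] - bvals[cur[1L]] <= tolerance) cur <- c(cur, i)
      else { shellIndex <- c(shellIndex, list(cur)); cur <- i }
    }
    shellIndex <- c(shellIndex, list(cur))
    shellB <- vapply(shellIndex, function(ix) mean(bvals[ix]), numeric(1))
    shellIndex <- lapply(shellIndex, function(ix) sort(ix))
  }
  new("GradientScheme", bval = as.numeric(bvals), dirs = dirs,
      shellB = shellB, shellIndex = shellIndex, b0Index = as.integer(sort(b0)))
}

#' Generate a multi-shell sampling scheme
#'
#' Builds per-shell direction sets by electrostatic-repulsion energy
#' minimization with antipodal symmetry (started from a deterministic
#' Fibonacci covering), each shell rotated by an independent uniformly
#' random rotation so the shells sample distinct directions; reproducible
#' under \code{seed}.  The default b-values are the 6-shell high-b protocol
#' (b = 900 to 6400 s/mm^2, linear in q) with 70 directions per shell and 30
#' interleaved b=0 volumes.
#'
#' @param bvalues shell b-values in s/mm^2.
#' @param dirsPerShell directions per shell (default 70).
#' @param nB0 number of b=0 volumes (default 30).
#' @param seed RNG seed for the shell rotations.
#' @return a [GradientScheme-class] with b=0 volumes first, then shells in
#'   ascending b order.
#' @examples
#' sch <- makeScheme(seed = 1)
#' length(bvalues(sch))  # 450 measurements
#' @export
makeScheme <- function(bvalues = c(900, 1600, 2500, 3600, 4900, 6400),
                       dirsPerShell = 70L, nB0 = 30L, seed = NULL) {
  stopifnot(dirsPerShell >= 1L, all(bvalues > 0))
  if (dirsPerShell < 6L)
    warning("fewer than 6 directions per shell: unusable for l > 0 fitting")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old))
    set.seed(seed)
  }
  base <- repulsionDirections(dirsPerShell)
  dirs <- matrix(0, nB0, 3)
  bv <- rep(0, nB0)
  for (b in sort(bvalues)) {
    R <- randomRotation()
    dirs <- rbind(dirs, base %*% t(R))
    bv <- c(bv, rep(b, dirsPerShell))
  }
  gradientScheme(bv, dirs, tolerance = min(50, min(bvalues) / 2))
}

restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Minimum pairwise angular separation of a direction set
#'
#' @param dirs numeric matrix (n x 3) of unit vectors.
#' @param antipodal treat opposite directions as identical (default TRUE,
#'   appropriate for diffusion gradients).
#' @return minimum pairwise angle in radians.
#' @export
minAngle <- function(dirs, antipodal = TRUE) {
  ct <- tcrossprod(dirs)
  if (antipodal) ct <- abs(ct)
  acos(min(max(ct[upper.tri(ct)]), 1))
}

#' Construct a standard-model kernel
#'
#' @param f intra-axonal signal fraction in [0, 1].
#' @param Di intra-axonal (stick) diffusivity (um^2/ms).
#' @param De extra-axonal axial diffusivity (um^2/ms).
#' @param Dr extra-axonal radial diffusivity (um^2/ms).
#' @return a [StandardModelKernel-class].
#' @details Defaults (f = 0.5, Di = 2.2, De = 2.0, Dr = 0.8 um^2/ms) are
#'   plausible adult white-matter values chosen as implementation defaults
#'   for simulation studies; they are configuration, not measured constants.
#' @export
stmKernel <- function(f = 0.5, Di = 2.2, De = 2.0, Dr = 0.8) {
  new("StandardModelKernel", f = f, Di = Di, De = De, Dr = Dr)
}

#' Evaluate the standard-model response
#'
#' Two-compartment signal of a coherent fibre population:
#' H(b, xi) = f exp(-b Di xi^2) + (1-f) exp(-b (Dr + (De - Dr) xi^2)),
#' where xi is the cosine of the angle between fibre and gradient, b is in
#' s/mm^2 and diffusivities in um^2/ms (so the products use b * D * 1e-3).
#'
#' @param kernel a [StandardModelKernel-class].
#' @param b b-value(s) in s/mm^2.
#' @param xi cosine(s) of the fibre-gradient angle, in [-1, 1].
#' @return signal in (0, 1]; 1 at b = 0.
#' @export
stmSignal <- function(kernel, b, xi) {
  stopifnot(is(kernel, "StandardModelKernel"), all(b >= 0))
  validObject(kernel)
  xi2 <- xi^2
  bb <- b * bUnit
  kernel@f * exp(-bb * kernel@Di * xi2) +
    (1 - kernel@f) * exp(-bb * (kernel@Dr + (kernel@De - kernel@Dr) * xi2))
}

#' Zonal SH coefficients of an axially symmetric kernel
#'
#' Projects H(b, xi) onto the zonal spherical harmonics Y_l^0 per shell by
#' Gauss-Legendre quadrature: hbar_{l,b} = 2 pi int_{-1}^{1} H(b, xi)
#' Ybar_l^0(xi) d xi.
#'
#' @param kernel a [StandardModelKernel-class].
#' @param bvalues shell b-values (s/mm^2), or a [GradientScheme-class] whose
#'   shell b-values are used.
#' @param lmax even maximum order (default 8).
#' @param nQuad quadrature order (default 256, ample for 1e-10 accuracy at
#'   the b-values of interest).
#' @return numeric matrix (k shells x number of even orders), columns
#'   l = 0, 2, ..., lmax.
#' @export
kernelToZonal <- function(kernel, bvalues, lmax = 8L, nQuad = 256L) {
  stopifnot(lmax %% 2 == 0)
  if (is(bvalues, "GradientScheme")) bvalues <- bvalues@shellB
  gl <- pracma::gaussLegendre(nQuad, -1, 1)
  P <- normLegendre(gl$x, lmax, 0L)          # Pbar_l^0, l = 0..lmax
  lvals <- seq.int(0, lmax, 2)
  out <- matrix(0, length(bvalues), length(lvals))
  for (i in seq_along(bvalues)) {
    H <- stmSignal(kernel, bvalues[i], gl$x)
    out[i, ] <- 2 * pi * colSums(gl$w * H * P[, lvals + 1L, drop = FALSE])
  }
  rownames(out) <- format(bvalues)
  colnames(out) <- paste0("l", lvals)
  out
}

#' Specify a fibre configuration
#'
#' @param kernels list of [StandardModelKernel-class] objects (recycled if a
#'   single kernel is given).
#' @param directions numeric matrix (n x 3) of fascicle orientations (unit
#'   vectors).
#' @param weights non-negative fascicle weights (default equal, summing to 1).
#' @param dispersion per-fascicle orientation dispersion: Laplace-Beltrami
#'   apodization exp(-dispersion * l (l+1)) of the fascicle's delta-function
#'   ODF (0 = coherent fascicle; ~0.01 is moderate).
#' @return a list of class \code{fibreConfig}.
#' @export
fibreConfig <- function(kernels, directions, weights = NULL, dispersion = 0) {
  directions <- rbind(directions)
  n <- nrow(directions)
  if (is(kernels, "StandardModelKernel")) kernels <- list(kernels)
  if (length(kernels) == 1L) kernels <- rep(kernels, n)
  stopifnot(length(kernels) == n, n >= 1L)
  nrm <- sqrt(rowSums(directions^2))
  stopifnot(all(abs(nrm - 1) < 1e-3))
  directions <- directions / nrm
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  dispersion <- rep(dispersion, length.out = n)
  structure(list(kernels = kernels, directions = directions,
                 weights = weights, dispersion = dispersion),
            class = "fibreConfig")
}

# Noise-free per-shell signal SH coefficients of a configuration: each
# fascicle is a (possibly apodized) SH delta ODF p_l^m = w * d_l * Y_l^m(n)
# convolved with its own kernel.
configCoefficients <- function(config, shellB, lmax = 8L) {
  lvals <- seq.int(0, lmax, 2)
  coef <- matrix(0, length(shellB), shNCoef(lmax))
  for (j in seq_along(config$weights)) {
    hbar <- kernelToZonal(config$kernels[[j]], shellB, lmax)
    Yn <- shBasis(config$directions[j, , drop = FALSE], lmax)[1L, ]
    att <- rep(exp(-config$dispersion[j] * lvals * (lvals + 1)),
               times = 2 * lvals + 1)
    coef <- coef + config$weights[j] * convolveSH(hbar, Yn * att)
  }
  coef
}

#' Simulate one voxel's multi-shell signal
#'
#' The noise-free signal is the sum over fascicles of each kernel convolved
#' with a delta-function ODF along the fascicle direction.  With
#' \code{odf = "projected"} (default) the delta ODFs are represented in the
#' even SH basis truncated at \code{lmax} (optionally apodized by the
#' configuration's dispersion), so the signal is exactly band-limited; with
#' \code{odf = "dense"} the response is evaluated directly as
#' sum_i w_i H_i(b, g . n_i), which carries angular content beyond any finite
#' lmax (truncation error then appears in subsequent fits, growing with b).
#'
#' @param config a [fibreConfig()].
#' @param scheme a [GradientScheme-class].
#' @param snr signal-to-noise ratio referenced to the voxel's noise-free b=0
#'   signal; \code{Inf} for noise-free.
#' @param noise "gaussian" (additive i.i.d., the post-denoising regime) or
#'   "rician" (magnitude of a complex Gaussian perturbation).
#' @param odf "projected" or "dense", see Details.
#' @param lmax band limit used by the projected representation.
#' @param seed optional RNG seed for the noise.
#' @return numeric vector of measurements ordered as the scheme (b=0 volumes
#'   included).
#' @export
simulateVoxel <- function(config, scheme, snr = Inf,
                          noise = c("gaussian", "rician"),
                          odf = c("projected", "dense"), lmax = 8L,
                          seed = NULL) {
  noise <- match.arg(noise)
  odf <- match.arg(odf)
  stopifnot(inherits(config, "fibreConfig"), is(scheme, "GradientScheme"),
            snr > 0)
  n <- length(scheme@bval)
  b0sig <- sum(config$weights)           # H(b=0) = 1 for every kernel
  y <- rep(b0sig, n)
  if (odf == "projected") {
    coef <- configCoefficients(config, scheme@shellB, lmax)
    for (b in seq_along(scheme@shellB)) {
      idx <- scheme@shellIndex[[b]]
      B <- shBasis(scheme@dirs[idx, , drop = FALSE], lmax)
      y[idx] <- B %*% coef[b, ]
    }
  } else {
    for (b in seq_along(scheme@shellB)) {
      idx <- scheme@shellIndex[[b]]
      xi <- scheme@dirs[idx, , drop = FALSE] %*% t(config$directions)
      s <- 0
      for (j in seq_along(config$weights))
        s <- s + config$weights[j] *
          stmSignal(config$kernels[[j]], scheme@shellB[b], xi[, j])
      y[idx] <- s
    }
  }
  if (is.finite(snr)) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restoreRNG(old))
      set.seed(seed)
    }
    sd <- b0sig / snr
    if (noise == "gaussian") {
      y <- y + rnorm(n, 0, sd)
    } else {
      y <- sqrt((y + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2)
    }
  }
  y
}

#' Detectability power surface for a two-fascicle crossing
#'
#' Sweeps a standard-model parameter difference Delta and the SNR for two
#' equally weighted fascicles crossing at 90 degrees, with kernels at the
#' baseline parameter value +/- Delta/2.  Each grid cell simulates
#' \code{nVoxels} voxels, runs the full decomposition and residual-bootstrap
#' permutation test, and records the fraction of voxels whose component-2
#' p-value falls below each significance level.
#'
#' Common random numbers are used across cells (the same per-voxel noise
#' realization, scaled to each SNR, and the same permutations), which
#' sharpens the monotone structure of the surface at fixed simulation size.
#'
#' @param param which kernel parameter differs: "f", "Di", "De" or "Dr".
#' @param deltas numeric vector of parameter differences (>= 0).
#' @param snrs numeric vector of SNR values.
#' @param baseline baseline [StandardModelKernel-class] (default
#'   [stmKernel()]).
#' @param nVoxels voxels per grid cell (default 100).
#' @param nPerm bootstrap instances per voxel (default 999).
#' @param alphas significance levels (default 0.05 and 0.001).
#' @param lmax SH order (default 8).
#' @param scheme sampling scheme (default [makeScheme()] under \code{seed}).
#' @param seed RNG seed.
#' @param crossingAngle angle between the fascicles in degrees (default 90).
#' @param leverageMode leverage scale, see [sampleNull()].
#' @return data.frame of class \code{powerSurface} with columns
#'   \code{delta}, \code{snr} and \code{rate_<alpha>}; attribute
#'   \code{contours} holds per-alpha 50% detection contours (SNR at which the
#'   interpolated detection rate crosses the level).
#' @export
powerSurface <- function(param = c("f", "Di", "De", "Dr"),
                         deltas = c(0, 0.3, 0.6),
                         snrs = c(25, 75, 225),
                         baseline = stmKernel(), nVoxels = 100L,
                         nPerm = 999L, alphas = c(0.05, 0.001), lmax = 8L,
                         scheme = NULL, seed = 1L, crossingAngle = 90,
                         leverageMode = c("sqrt", "linear")) {
  param <- match.arg(param)
  leverageMode <- match.arg(leverageMode)
  stopifnot(length(deltas) >= 1L, length(snrs) >= 1L, nVoxels >= 1L)
  if (is.null(scheme)) scheme <- makeScheme(seed = seed)
  design <- schemeDesign(scheme, lmax)
  a <- crossingAngle * pi / 180
  dirA <- c(0, 0, 1); dirB <- c(sin(a), 0, cos(a))
  n <- length(scheme@bval)
  grid <- expand.grid(delta = sort(deltas), snr = sort(snrs))
  rates <- matrix(0, nrow(grid), length(alphas))
  # common random numbers: one noise draw and one permutation stream per voxel
  old <- globalenv()$.Random.seed
  on.exit(restoreRNG(old))
  set.seed(seed)
  eps <- matrix(rnorm(n * nVoxels), n, nVoxels)
  permSeeds <- sample.int(.Machine$integer.max - 1L, nVoxels)
  cleanCache <- new.env()
  for (d in sort(deltas)) {
    pars <- c(f = baseline@f, Di = baseline@Di, De = baseline@De,
              Dr = baseline@Dr)
    pA <- pars; pA[param] <- pA[param] - d / 2
    pB <- pars; pB[param] <- pB[param] + d / 2
    if (param == "f") { pA["f"] <- max(pA["f"], 0); pB["f"] <- min(pB["f"], 1) }
    cfg <- fibreConfig(list(do.call(stmKernel, as.list(pA)),
                            do.call(stmKernel, as.list(pB))),
                       rbind(dirA, dirB), weights = c(0.5, 0.5))
    clean <- simulateVoxel(cfg, scheme, snr = Inf, lmax = lmax)
    for (s in sort(snrs)) {
      row <- which(grid$delta == d & grid$snr == s)
      p2 <- numeric(nVoxels)
      for (vx in seq_len(nVoxels)) {
        y <- clean + eps[, vx] / s          # b0 signal is 1 by construction
        res <- testVoxel(y, design, nPerm = nPerm, seed = permSeeds[vx],
                         leverageMode = leverageMode)
        p2[vx] <- res$p[1L]
      }
      rates[row, ] <- vapply(alphas, function(al) mean(p2 < al), numeric(1))
    }
  }
  colnames(rates) <- paste0("rate_", alphas)
  out <- cbind(grid, rates)
  attr(out, "contours") <- powerContours(out, alphas, level = 0.5)
  attr(out, "param") <- param
  class(out) <- c("powerSurface", "data.frame")
  out
}

# Interpolated SNR at which the detection rate crosses `level`, per delta and
# alpha (log-SNR linear interpolation); NA when the rate never crosses.
powerContours <- function(grid, alphas, level = 0.5) {
  out <- list()
  for (al in alphas) {
    rc <- paste0("rate_", al)
    res <- vapply(sort(unique(grid$delta)), function(d) {
      g <- grid[grid$delta == d, ]
      g <- g[order(g$snr), ]
      r <- g[[rc]]
      if (all(r < level) || r[1L] >= level) return(NA_real_)
      i <- which(r >= level)[1L]
      x0 <- log(g$snr[i - 1L]); x1 <- log(g$snr[i])
      exp(x0 + (level - r[i - 1L]) / (r[i] - r[i - 1L]) * (x1 - x0))
    }, numeric(1))
    out[[as.character(al)]] <- data.frame(delta = sort(unique(grid$delta)),
                                          snr50 = res)
  }
  out
}

#' Write a power surface to CSV
#'
#' @param surface a [powerSurface()] result.
#' @param path output CSV path.
#' @export
writePowerSurface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.powerSurface <- function(x, alpha = NULL, ...) {
  rcols <- grep("^rate_", names(x), value = TRUE)
  if (is.null(alpha)) alpha <- sub("rate_", "", rcols[1L])
  z <- stats::xtabs(stats::as.formula(paste0("rate_", alpha, " ~ delta + snr")),
                    data = x)
  graphics::contour(sort(unique(x$delta)), sort(unique(x$snr)), z,
                    xlab = sprintf("delta(%s)", attr(x, "param")),
                    ylab = "SNR", ...)
  invisible(x)
}
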