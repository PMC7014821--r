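# Residual-bootstrap permutation test of the single-convolution (rank-1)
# assumption: leverage factor, null sampling, p-values, FDR over voxel maps.

#' Leverage factor of the rank-1 fit
#'
#' The rank-1 model spends kappa = sum_{l even <= lmax} [k + (2l+1) - 1]
#' degrees of freedom (per order: k shell loadings + 2l+1 ODF loadings - 1
#' scale ambiguity) on nu = k x directions-per-shell data points; h =
#' kappa/nu.  For the 6-shell, 70-direction, lmax = 8 protocol this gives
#' kappa = 70, nu = 420 and h = 1/6.
#'
#' @param k number of diffusion-weighted shells.
#' @param lmax even maximum SH order.
#' @param dirsPerShell directions per shell.
#' @return a [LeverageSpec-class].
#' @examples
#' leverageFactor(6, 8, 70)  # kappa = 70, nu = 420, h = 1/6
#' @export
leverageFactor <- function(k, lmax, dirsPerShell) {
  stopifnot(k >= 1, lmax %% 2 == 0, lmax >= 0)
  lvals <- seq.int(0, lmax, 2)
  if (dirsPerShell < shNCoef(lmax))
    stop(sprintf("dirsPerShell (%d) below the basis size (%d): fit under-determined",
                 dirsPerShell, shNCoef(lmax)))
  kappa <- sum(k + (2 * lvals + 1) - 1)
  nu <- k * dirsPerShell
  new("LeverageSpec", kappa = as.integer(kappa), nu = as.integer(nu),
      h = kappa / nu)
}

setMethod("show", "LeverageSpec", function(object) {
  cat(sprintf("LeverageSpec: kappa = %d, nu = %d, h = %.6g\n",
              object@kappa, object@nu, object@h))
})

leverageScale <- function(h, mode = c("sqrt", "linear")) {
  mode <- match.arg(mode)
  if (mode == "sqrt") 1 / sqrt(1 - h) else 1 / (1 - h)
}

#' Sample the null distribution of component effect sizes
#'
#' Residual-bootstrap under the null that components beyond the first carry
#' no structure.  Each instance applies a uniformly random permutation Pi to
#' the rank-1 residuals (one flat permutation over all nu diffusion-weighted
#' entries), rescales them to undo the leverage deflation of the residual
#' variance, forms y' = yhat + scale * Pi e, refits the SH coefficients per
#' shell, rebuilds the per-order matrices and stores their pooled singular
#' values sigma'_i.
#'
#' The rescaling default is the variance-restoring factor 1/sqrt(1-h) (mode
#' \code{"sqrt"}): an ordinary least-squares fit deflates the mean squared
#' residual to (1 - h) times the noise variance, so dividing the residuals
#' by sqrt(1-h) restores the noise level.  The alternative factor 1/(1-h)
#' (mode \code{"linear"}) over-restores the variance by 1/(1-h) and is
#' provided for comparison.
#'
#' @param fit a \code{rank1Fit} from [rank1Reconstruct()].
#' @param scheme the [GradientScheme-class] of the fit.
#' @param lmax even maximum SH order.
#' @param nPerm number of bootstrap instances N (>= 1).
#' @param seed RNG seed (instances are reproducible given the seed).
#' @param leverageMode "sqrt" (default) or "linear", see above.
#' @param replace resample residuals with replacement instead of permuting
#'   (default FALSE: a true permutation).
#' @param keepInstances also return the rescaled permuted residuals e' as an
#'   attribute \code{"instances"} (nu x nPerm matrix); memory-hungry, meant
#'   for diagnostics.
#' @param design optional precomputed design (internal fast path).
#' @return a [NullSamples-class].
#' @export
sampleNull <- function(fit, scheme, lmax = 8L, nPerm = 999L, seed = 1L,
                       leverageMode = c("sqrt", "linear"), replace = FALSE,
                       keepInstances = FALSE, design = NULL) {
  leverageMode <- match.arg(leverageMode)
  stopifnot(inherits(fit, "rank1Fit"))
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (is.null(design)) design <- schemeDesign(scheme, lmax)
  nu <- length(design$dwiIndex)
  if (length(fit$yhat) != nu)
    stop("fit does not match the scheme (different number of DWI measurements)")
  dps <- lengths(design$scheme@shellIndex)
  if (length(unique(dps)) != 1L)
    stop("leverage bookkeeping requires equal directions per shell")
  spec <- leverageFactor(design$k, design$lmax, dps[1L])
  scale <- leverageScale(spec@h, leverageMode)
  old <- globalenv()$.Random.seed
  on.exit(restoreRNG(old))
  set.seed(seed)
  perms <- vapply(seq_len(nPerm), function(j)
    if (replace) sample.int(nu, nu, replace = TRUE) else sample.int(nu),
    integer(nu))
  sig <- cppNullSigmas(fit$yhat, fit$resid, perms, scale, design$pinv,
                       design$shellPos, design$blockSizes)
  colnames(sig) <- paste0("sigma", seq_len(ncol(sig)))
  out <- new("NullSamples", sigma = sig, nPerm = as.integer(nPerm),
             seed = as.integer(seed), leverageMode = leverageMode,
             replace = replace)
  if (keepInstances)
    attr(out, "instances") <- scale * matrix(fit$resid[perms], nrow(perms))
  out
}

setMethod("show", "NullSamples", function(object) {
  cat(sprintf(
    "NullSamples: %d bootstrap instances x %d components (seed %d, %s leverage%s)\n",
    object@nPerm, ncol(object@sigma), object@seed, object@leverageMode,
    if (object@replace) ", with replacement" else ""))
})

#' Permutation p-values of components beyond the first
#'
#' P_i = 1 - (N_i+ + 1)/(N + 1), where N_i+ counts bootstrap instances whose
#' effect size is strictly exceeded by the data (sigma_i > sigma'_i; ties
#' count as not exceeded).  Values lie in [0, N/(N+1)]: the add-one structure
#' never returns exactly 1.
#'
#' @param sigma pooled data effect sizes (vector, component i in position i),
#'   or a [ShardDecomposition-class].
#' @param null a [NullSamples-class] for the same voxel.
#' @param components which components to test (default all i >= 2 available).
#' @return named numeric vector of p-values, names \code{P2, P3, ...}.
#' @export
permPValues <- function(sigma, null, components = NULL) {
  if (is(sigma, "ShardDecomposition")) sigma <- sigma@sigma
  stopifnot(is(null, "NullSamples"))
  r <- min(length(sigma), ncol(null@sigma))
  if (is.null(components)) components <- seq.int(2L, r)
  stopifnot(all(components >= 2L), all(components <= r))
  N <- null@nPerm
  p <- vapply(components, function(i) {
    nPlus <- sum(sigma[i] > null@sigma[, i])
    1 - (nPlus + 1) / (N + 1)
  }, numeric(1))
  names(p) <- paste0("P", components)
  p
}

#' Benjamini-Hochberg FDR correction over a voxel map
#'
#' Standard BH step-up over all in-mask p-values of one component: with m
#' ordered p-values, reject the smallest j such that p_(j) <= j/m * q for the
#' largest such j (equivalently, adjusted p <= q via [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in [0, 1] (one per in-mask voxel).
#' @param q FDR level (default 0.05).
#' @return logical vector: TRUE where the voxel is a discovery.
#' @export
fdrCorrect <- function(p, q = 0.05) {
  if (!length(p)) {
    warning("empty p-value map: no voxels to correct")
    return(logical(0))
  }
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

# Decompose + rank-1 + permutation test for one voxel. Returns pooled data
# sigmas, R and the p-values of the requested components.
testVoxel <- function(y, design, nPerm = 999L, seed = 1L,
                      leverageMode = "sqrt", components = 2L,
                      normalizeB0 = FALSE) {
  coef <- fitShellSH(y, NULL, design$lmax, normalizeB0 = normalizeB0,
                     design = design)
  dec <- shardDecompose(coef, design$lmax, shellB = design$scheme@shellB)
  fit <- rank1Reconstruct(dec, y, NULL, design = design)
  null <- sampleNull(fit, NULL, design$lmax, nPerm = nPerm, seed = seed,
                     leverageMode = leverageMode, design = design)
  p <- permPValues(dec, null, components = components)
  list(sigma = dec@sigma, R = dec@R, p = p, dec = dec, fit = fit)
}
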