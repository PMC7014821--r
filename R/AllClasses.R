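#' @import methods
NULL

#' Multi-shell gradient scheme
#'
#' Container for a diffusion-weighted sampling scheme: one b-value and one
#' unit gradient direction per measurement, plus the shell grouping derived
#' from the b-values.  Measurements with b below the grouping tolerance are
#' treated as b=0 volumes; they never enter the per-shell spherical-harmonic
#' fits but may be used for signal normalization.
#'
#' @slot bval numeric vector of b-values (s/mm^2), one per measurement.
#' @slot dirs numeric matrix (n x 3) of unit gradient directions.
#' @slot shellB numeric vector of the k grouped shell b-values (mean within
#'   group), strictly positive and increasing.
#' @slot shellIndex list of k integer vectors: measurement indices per shell.
#' @slot b0Index integer vector of b=0 measurement indices.
#'
#' @seealso [makeScheme()], [readGradients()], [gradientScheme()]
#' @exportClass GradientScheme
setClass("GradientScheme",
  representation(
    bval = "numeric",
    dirs = "matrix",
    shellB = "numeric",
    shellIndex = "list",
    b0Index = "integer"
  )
)

setValidity("GradientScheme", function(object) {
  msg <- character()
  n <- length(object@bval)
  if (nrow(object@dirs) != n || ncol(object@dirs) != 3L)
    msg <- c(msg, "dirs must be an n x 3 matrix matching length(bval)")
  if (length(object@shellB) != length(object@shellIndex))
    msg <- c(msg, "shellB and shellIndex lengths differ")
  if (length(object@shellB) && is.unsorted(object@shellB, strictly = TRUE))
    msg <- c(msg, "shell b-values must be distinct and increasing")
  if (any(object@shellB <= 0))
    msg <- c(msg, "shell b-values must be strictly positive")
  covered <- sort(c(unlist(object@shellIndex), object@b0Index))
  if (!identical(covered, seq_len(n)))
    msg <- c(msg, "shellIndex + b0Index must partition the measurements")
  dw <- unlist(object@shellIndex)
  if (length(dw)) {
    nrm <- sqrt(rowSums(object@dirs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "diffusion-weighted directions must have unit norm (1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Two-compartment standard-model kernel
#'
#' Axially symmetric white-matter response: an intra-axonal "stick" with
#' signal fraction \code{f} and diffusivity \code{Di}, plus an extra-axonal
#' axially symmetric tensor ("zeppelin") with axial diffusivity \code{De} and
#' radial diffusivity \code{Dr}.  Diffusivities are in micrometer^2/ms; the
#' kernel evaluates to 1 at b = 0.
#'
#' @slot f intra-axonal signal fraction in [0, 1].
#' @slot Di intra-axonal (stick) diffusivity (um^2/ms).
#' @slot De extra-axonal axial diffusivity (um^2/ms).
#' @slot Dr extra-axonal radial diffusivity (um^2/ms), Dr <= De.
#'
#' @seealso [stmKernel()], [stmSignal()], [kernelToZonal()]
#' @exportClass StandardModelKernel
setClass("StandardModelKernel",
  representation(f = "numeric", Di = "numeric", De = "numeric", Dr = "numeric")
)

setValidity("StandardModelKernel", function(object) {
  msg <- character()
  for (s in c("f", "Di", "De", "Dr"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("slot '%s' must be a finite scalar", s))
  if (!length(msg)) {
    if (object@f < 0 || object@f > 1)
      msg <- c(msg, "intra-axonal fraction f must lie in [0, 1]")
    if (object@Di < 0 || object@De < 0 || object@Dr < 0)
      msg <- c(msg, "diffusivities must be non-negative")
    if (object@De < object@Dr)
      msg <- c(msg, "axial diffusivity De must be >= radial diffusivity Dr")
  }
  if (length(msg)) msg else TRUE
})

#' Voxel-wise SHARD decomposition
#'
#' Result of the per-voxel singular value decomposition of the shell-by-order
#' coefficient matrices S_l (one per even spherical-harmonic order l <= lmax;
#' k shells in rows, 2l+1 coefficients in columns).  Component effect sizes
#' are pooled across orders as sigma_i^2 = sum_l sigma_{l,i}^2 and the ratio
#' R = sigma_1^2 / sum_i sigma_i^2 * 100 measures the percentage of signal
#' power explained by the leading (rank-1) component.
#'
#' @slot lmax even spherical-harmonic order of the fit.
#' @slot shellB shell b-values (row order of every S_l).
#' @slot sigmaL list per order l: singular values, descending.
#' @slot u list per order l: left singular vectors (k x r_l), columns i.
#' @slot v list per order l: right singular vectors ((2l+1) x r_l).
#' @slot sigma pooled component effect sizes sigma_i (RMS signal units).
#' @slot R percentage of signal power in the leading component, in [0, 100].
#' @slot degenerate TRUE when the voxel signal was all zero and R = 100 was
#'   assigned by convention.
#'
#' @seealso [shardDecompose()], [pooledSigma()], [powerRatio()]
#' @exportClass ShardDecomposition
setClass("ShardDecomposition",
  representation(
    lmax = "integer",
    shellB = "numeric",
    sigmaL = "list",
    u = "list",
    v = "list",
    sigma = "numeric",
    R = "numeric",
    degenerate = "logical"
  )
)

setValidity("ShardDecomposition", function(object) {
  msg <- character()
  for (sv in object@sigmaL) {
    if (any(sv < 0)) msg <- c(msg, "singular values must be non-negative")
    if (is.unsorted(rev(sv))) msg <- c(msg, "singular values must be descending")
  }
  if (length(object@R) != 1L || object@R < 0 || object@R > 100 + 1e-9)
    msg <- c(msg, "R must be a scalar percentage in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Leverage specification of the rank-1 least-squares model
#'
#' Degrees-of-freedom bookkeeping for the residual-bootstrap test: the rank-1
#' model spends kappa = sum_l [k + (2l+1) - 1] degrees of freedom (per order:
#' k shell loadings plus 2l+1 coefficient loadings minus one scale ambiguity)
#' on nu = k * directions-per-shell data points, giving leverage h = kappa/nu.
#'
#' @slot kappa model degrees of freedom.
#' @slot nu number of diffusion-weighted data points per voxel.
#' @slot h leverage factor kappa/nu, in (0, 1).
#'
#' @seealso [leverageFactor()]
#' @exportClass LeverageSpec
setClass("LeverageSpec",
  representation(kappa = "integer", nu = "integer", h = "numeric")
)

setValidity("LeverageSpec", function(object) {
  if (object@h <= 0 || object@h >= 1)
    "leverage h must lie strictly between 0 and 1 (model must be over-determined)"
  else TRUE
})

#' Null samples of component effect sizes
#'
#' Effect sizes sigma'_i obtained by refitting residual-bootstrap instances
#' y' = yhat + scale * Pi e, where Pi is a random permutation of the rank-1
#' residuals and scale restores the residual variance deflated by leverage.
#'
#' @slot sigma numeric matrix (nPerm x r) of bootstrap effect sizes; column i
#'   holds the null distribution of component i.
#' @slot nPerm number of bootstrap instances.
#' @slot seed RNG seed used.
#' @slot leverageMode "sqrt" for the variance-restoring scale 1/sqrt(1-h) or
#'   "linear" for 1/(1-h).
#' @slot replace TRUE when residuals were resampled with replacement instead
#'   of permuted.
#'
#' @seealso [sampleNull()], [permPValues()]
#' @exportClass NullSamples
setClass("NullSamples",
  representation(
    sigma = "matrix",
    nPerm = "integer",
    seed = "integer",
    leverageMode = "character",
    replace = "logical"
  )
)

#' Map set produced by whole-image runs
#'
#' 3-D voxel maps sharing the grid of the input image, plus the parameters
#' needed to reproduce the run.  Maps present depend on the producing call:
#' \code{sigma1} (RMS signal power of the leading component), \code{residRMS}
#' (RMS power in components beyond the first), \code{R} (% power explained),
#' and per tested component \code{p<i>} and FDR masks \code{sig<i>}.
#'
#' @slot maps named list of 3-D arrays (and logical arrays for FDR masks).
#' @slot params named list of run parameters (lmax, seed, alpha, ...).
#'
#' @seealso [runDecompose()], [runTest()], [writeMaps()]
#' @exportClass ShardMaps
setClass("ShardMaps",
  representation(maps = "list", params = "list")
)
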