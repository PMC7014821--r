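# File formats and whole-image orchestration: gradient tables, NIfTI-1 I/O,
# voxel-wise decomposition and permutation-test maps.

#' Read a gradient table
#'
#' Accepts either an FSL bvals/bvecs pair (bvecs as 3 x N or N x 3, detected
#' automatically) or a single 4-column whitespace table (x y z b).
#'
#' @param bvals path to the bvals file, or to the 4-column table when
#'   \code{bvecs} is missing.
#' @param bvecs path to the bvecs file (omit for the 4-column format).
#' @param tolerance shell grouping tolerance in s/mm^2 (default 50).
#' @return a [GradientScheme-class].
#' @export
readGradients <- function(bvals, bvecs = NULL, tolerance = 50) {
  if (is.null(bvecs)) {
    tab <- as.matrix(utils::read.table(bvals))
    if (ncol(tab) != 4L)
      stop(sprintf("gradient table %s has %d columns; expected 4 (x y z b)",
                   bvals, ncol(tab)))
    return(gradientScheme(tab[, 4L], tab[, 1:3], tolerance = tolerance))
  }
  bv <- scan(bvals, quiet = TRUE)
  vec <- as.matrix(utils::read.table(bvecs))
  if (nrow(vec) == 3L && ncol(vec) != 3L) vec <- t(vec)
  if (ncol(vec) != 3L)
    stop(sprintf("bvecs %s is %d x %d; expected 3 x N or N x 3",
                 bvecs, nrow(vec), ncol(vec)))
  if (nrow(vec) != length(bv))
    stop(sprintf("bvals has %d entries but bvecs has %d vectors",
                 length(bv), nrow(vec)))
  gradientScheme(bv, vec, tolerance = tolerance)
}

#' Write a gradient scheme as FSL bvals/bvecs
#'
#' @param scheme a [GradientScheme-class].
#' @param bvals,bvecs output paths (bvecs written 3 x N).
#' @export
writeGradients <- function(scheme, bvals, bvecs) {
  stopifnot(is(scheme, "GradientScheme"))
  cat(paste(format(scheme@bval, trim = TRUE), collapse = " "), "\n",
      file = bvals, sep = "")
  vec <- t(scheme@dirs)
  utils::write.table(format(vec, digits = 10, trim = TRUE), bvecs,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bvals, bvecs))
}

#' Simulate a 4-D image of independent voxels
#'
#' Fills an x * y * z grid with voxels drawn from one or more fibre
#' configurations; per-voxel noise seeds are derived from the voxel's linear
#' index so results do not depend on traversal order.
#'
#' @param configs a single [fibreConfig()] or a list of them.
#' @param assignment integer 3-D array (or vector of length prod(dim)) giving
#'   the config index per voxel; 0 marks background (zero signal).  Default:
#'   all voxels use config 1.
#' @param dim image dimensions (default c(5, 5, 4)).
#' @param scheme a [GradientScheme-class].
#' @param snr,noise,odf,lmax passed to [simulateVoxel()].
#' @param seed base seed; the per-voxel seed mixes in the voxel index.
#' @return list with \code{data} (4-D array), \code{mask} (logical 3-D
#'   array, TRUE where signal was simulated) and \code{assignment}.
#' @export
simulateImage <- function(configs, assignment = NULL, dim = c(5, 5, 4),
                          scheme = NULL, snr = Inf, noise = "gaussian",
                          odf = "projected", lmax = 8L, seed = 1L) {
  if (inherits(configs, "fibreConfig")) configs <- list(configs)
  if (is.null(scheme)) scheme <- makeScheme(seed = seed)
  nvox <- prod(dim)
  if (is.null(assignment)) assignment <- rep(1L, nvox)
  assignment <- as.integer(assignment)
  stopifnot(length(assignment) == nvox,
            all(assignment >= 0L), all(assignment <= length(configs)))
  n <- length(scheme@bval)
  data <- array(0, c(dim, n))
  flat <- matrix(0, nvox, n)
  # noise-free templates per config, noise added per voxel
  templates <- lapply(configs, simulateVoxel, scheme = scheme, snr = Inf,
                      odf = odf, lmax = lmax)
  for (vx in which(assignment > 0L)) {
    cfg <- configs[[assignment[vx]]]
    y <- templates[[assignment[vx]]]
    if (is.finite(snr)) {
      set.seed(mixSeed(seed, vx))
      b0sig <- sum(cfg$weights)
      sd <- b0sig / snr
      if (noise == "gaussian") y <- y + rnorm(n, 0, sd)
      else y <- sqrt((y + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2)
    }
    flat[vx, ] <- y
  }
  data[] <- flat
  list(data = data, mask = array(assignment > 0L, dim),
       assignment = array(assignment, dim), scheme = scheme)
}

# Deterministic per-voxel seed below 2^31, mixing the base seed and the
# voxel's linear index (Lehmer-style) so any traversal order gives identical
# results.
mixSeed <- function(seed, index) {
  m <- 2147483647
  s <- ((as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807) %% m
  as.integer(s)
}

asImageArray <- function(image) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  arr <- as.array(image)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D volume, got %d dimensions", length(dim(arr))))
  arr
}

asMaskArray <- function(mask, dim3) {
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  arr <- as.array(mask)
  if (length(dim(arr)) < 3L)                # NIfTI drops singleton dims
    dim(arr) <- c(dim(arr), rep(1L, 3L - length(dim(arr))))
  if (!identical(as.integer(dim(arr)[1:3]), as.integer(dim3)))
    stop(sprintf("mask grid (%s) does not match image grid (%s)",
                 paste(dim(arr), collapse = "x"),
                 paste(dim3, collapse = "x")))
  arr != 0
}

#' Voxel-wise SHARD decomposition over an image
#'
#' Runs fit -> per-order matrices -> SVD in every in-mask voxel and returns
#' maps of the leading-component RMS signal power sigma_1, the total RMS
#' power in components beyond the first, and the percentage of signal power
#' explained R.
#'
#' @param image 4-D array or path to a NIfTI-1 volume (x, y, z, measurement).
#' @param scheme a [GradientScheme-class] matching the measurement axis.
#' @param mask logical/numeric 3-D array or NIfTI path; default: all voxels.
#' @param lmax even maximum SH order (default 8).
#' @param normalizeB0 divide by mean b=0 signal before fitting.
#' @param background value written outside the mask (default NA).
#' @param verbose print progress (default FALSE).
#' @return a [ShardMaps-class] with maps \code{sigma1}, \code{residRMS},
#'   \code{R} and \code{degenerate}.
#' @export
runDecompose <- function(image, scheme, mask = NULL, lmax = 8L,
                         normalizeB0 = FALSE, background = NA_real_,
                         verbose = FALSE) {
  arr <- asImageArray(image)
  d3 <- dim(arr)[1:3]
  if (dim(arr)[4L] != length(scheme@bval))
    stop(sprintf("image has %d measurements but the scheme has %d",
                 dim(arr)[4L], length(scheme@bval)))
  mask <- if (is.null(mask)) array(TRUE, d3) else asMaskArray(mask, d3)
  design <- schemeDesign(scheme, lmax)
  flat <- matrix(arr, prod(d3), dim(arr)[4L])
  idx <- which(mask)
  sigma1 <- residRMS <- Rmap <- array(background, d3)
  degen <- array(FALSE, d3)
  for (ii in seq_along(idx)) {
    vx <- idx[ii]
    coef <- fitShellSH(flat[vx, ], NULL, lmax, normalizeB0 = normalizeB0,
                       design = design)
    dec <- shardDecompose(coef, lmax, shellB = scheme@shellB)
    sigma1[vx] <- dec@sigma[1L]
    residRMS[vx] <- sqrt(sum(dec@sigma[-1L]^2))
    Rmap[vx] <- dec@R
    degen[vx] <- dec@degenerate
    if (verbose && ii %% 1000L == 0L)
      message(sprintf("decomposed %d / %d voxels", ii, length(idx)))
  }
  new("ShardMaps",
      maps = list(sigma1 = sigma1, residRMS = residRMS, R = Rmap,
                  degenerate = degen),
      params = list(op = "decompose", lmax = as.integer(lmax),
                    normalizeB0 = normalizeB0,
                    shellB = scheme@shellB, nMasked = length(idx),
                    version = as.character(utils::packageVersion("shardvox"))))
}

#' Voxel-wise permutation test over an image
#'
#' Runs the full pipeline (fit, decomposition, rank-1 reconstruction,
#' residual-bootstrap null, p-values) in every in-mask voxel and applies
#' Benjamini-Hochberg FDR per tested component across the mask.  Per-voxel
#' RNG seeds are derived from the base seed and the voxel's linear index, so
#' any traversal or parallel execution order yields identical maps.
#'
#' @inheritParams runDecompose
#' @param nPerm bootstrap instances per voxel (default 10000; values below
#'   99 trigger a warning about p-value resolution).
#' @param seed base RNG seed.
#' @param alpha significance level recorded with the maps (default 0.05).
#' @param fdr FDR level for the BH correction (default 0.05).
#' @param components components to test (default 2).
#' @param leverageMode "sqrt" (default) or "linear", see [sampleNull()].
#' @return a [ShardMaps-class] with maps \code{sigma1}, \code{residRMS},
#'   \code{R}, plus \code{p<i>} and logical \code{sig<i>} per component.
#' @export
runTest <- function(image, scheme, mask = NULL, lmax = 8L, nPerm = 10000L,
                    seed = 1L, alpha = 0.05, fdr = 0.05, components = 2L,
                    leverageMode = c("sqrt", "linear"), normalizeB0 = FALSE,
                    background = NA_real_, verbose = FALSE) {
  leverageMode <- match.arg(leverageMode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (nPerm < 99L)
    warning("nPerm < 99 gives very coarse p-value resolution")
  arr <- asImageArray(image)
  d3 <- dim(arr)[1:3]
  if (dim(arr)[4L] != length(scheme@bval))
    stop(sprintf("image has %d measurements but the scheme has %d",
                 dim(arr)[4L], length(scheme@bval)))
  mask <- if (is.null(mask)) array(TRUE, d3) else asMaskArray(mask, d3)
  design <- schemeDesign(scheme, lmax)
  flat <- matrix(arr, prod(d3), dim(arr)[4L])
  idx <- which(mask)
  maps <- list(sigma1 = array(background, d3),
               residRMS = array(background, d3),
               R = array(background, d3))
  pmat <- matrix(NA_real_, length(idx), length(components))
  for (ii in seq_along(idx)) {
    vx <- idx[ii]
    res <- testVoxel(flat[vx, ], design, nPerm = nPerm,
                     seed = mixSeed(seed, vx), leverageMode = leverageMode,
                     components = components, normalizeB0 = normalizeB0)
    maps$sigma1[vx] <- res$sigma[1L]
    maps$residRMS[vx] <- sqrt(sum(res$sigma[-1L]^2))
    maps$R[vx] <- res$R
    pmat[ii, ] <- res$p
    if (verbose && ii %% 100L == 0L)
      message(sprintf("tested %d / %d voxels", ii, length(idx)))
  }
  for (j in seq_along(components)) {
    comp <- components[j]
    pm <- array(background, d3)
    pm[idx] <- pmat[, j]
    maps[[paste0("p", comp)]] <- pm
    sig <- array(FALSE, d3)
    sig[idx] <- fdrCorrect(pmat[, j], q = fdr)
    maps[[paste0("sig", comp)]] <- sig
  }
  new("ShardMaps", maps = maps,
      params = list(op = "test", lmax = as.integer(lmax),
                    nPerm = as.integer(nPerm), seed = as.integer(seed),
                    alpha = alpha, fdr = fdr,
                    components = as.integer(components),
                    leverageMode = leverageMode, normalizeB0 = normalizeB0,
                    shellB = scheme@shellB, nMasked = length(idx),
                    version = as.character(utils::packageVersion("shardvox"))))
}

setMethod("show", "ShardMaps", function(object) {
  cat(sprintf("ShardMaps (%s): %s\n", object@params$op,
              paste(names(object@maps), collapse = ", ")))
  d <- dim(object@maps[[1L]])
  cat(sprintf("  grid %s, %d voxels in mask\n",
              paste(d, collapse = " x "), object@params$nMasked))
})

#' @describeIn ShardMaps extract one named map as a 3-D array.
#' @param x a \code{ShardMaps}.
#' @param name map name, e.g. "R", "p2", "sig2".
#' @export
getMap <- function(x, name) {
  stopifnot(is(x, "ShardMaps"))
  if (!name %in% names(x@maps))
    stop(sprintf("no map '%s'; available: %s", name,
                 paste(names(x@maps), collapse = ", ")))
  x@maps[[name]]
}

#' Write maps as NIfTI-1 volumes with a JSON provenance sidecar
#'
#' Continuous maps are written as float32 NIfTI, FDR masks as uint8; all run
#' parameters (lmax, seed, nPerm, shell b-values, package version, ...) go to
#' \code{<prefix>.json}.
#'
#' @param maps a [ShardMaps-class].
#' @param prefix output path prefix; each map goes to
#'   \code{<prefix>_<name>.nii.gz}.
#' @param template optional NIfTI image or path whose header (affine, voxel
#'   size) the outputs copy.
#' @return invisibly, the vector of files written.
#' @export
writeMaps <- function(maps, prefix, template = NULL) {
  stopifnot(is(maps, "ShardMaps"))
  if (is.character(template)) template <- RNifti::readNifti(template)
  files <- character()
  for (nm in names(maps@maps)) {
    m <- maps@maps[[nm]]
    isMask <- is.logical(m)
    arr <- if (isMask) array(as.integer(m), dim(m)) else m
    img <- if (is.null(template)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = template)
    path <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(img, path,
                       datatype = if (isMask) "uint8" else "float")
    files <- c(files, path)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(maps@params, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, sidecar))
}
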