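# Voxel-wise SHARD: per-order shell x coefficient matrices, their SVDs,
# pooled effect sizes and the rank-1 reconstruction.

#' Arrange per-shell SH coefficients into per-order matrices
#'
#' For each even order l <= lmax, collects the coefficients of that order
#' across shells into a matrix S_l with the k shells in rows and the 2l+1
#' coefficients (m = -l..l) in columns.  S_0 always has a single column and
#' hence rank 1: the l = 0 band cannot distinguish multiple kernels.
#'
#' @param coef numeric matrix (k shells x \code{shNCoef(lmax)}) as returned
#'   by [fitShellSH()]; all shells must share one lmax (enforced by the
#'   layout).
#' @param lmax even maximum order; inferred from \code{ncol(coef)} when
#'   missing.
#' @return named list of matrices \code{S0, S2, ...}.
#' @export
buildShardMatrices <- function(coef, lmax = NULL) {
  coef <- rbind(coef)
  if (is.null(lmax)) {
    lmax <- (sqrt(8 * ncol(coef) + 1) - 3) / 2
    if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
      stop(sprintf(
        "coefficient count %d does not match any even lmax layout", ncol(coef)))
    lmax <- as.integer(round(lmax))
  }
  if (ncol(coef) != shNCoef(lmax))
    stop(sprintf("coefficient count %d inconsistent with lmax = %d (need %d)",
                 ncol(coef), lmax, shNCoef(lmax)))
  lvals <- seq.int(0, lmax, 2)
  S <- lapply(lvals, function(l)
    coef[, shIndex(l, -l):shIndex(l, l), drop = FALSE])
  names(S) <- paste0("S", lvals)
  S
}

#' Voxel-wise SHARD decomposition
#'
#' Computes the singular value decomposition S_l = sum_i u_{l,i} sigma_{l,i}
#' v_{l,i}' of every per-order matrix, pools the component effect sizes
#' across orders as sigma_i^2 = sum_l sigma_{l,i}^2, and computes the
#' percentage of signal power explained by the leading component,
#' R = sigma_1^2 / sum_i sigma_i^2 * 100.  Under a single-convolution
#' (one kernel, one ODF) signal and no noise every S_l is rank 1 and
#' R = 100%.
#'
#' Components are paired across orders purely by singular-value index i.
#' Singular vectors are sign-fixed so the largest-magnitude entry of each
#' u_{l,i} is positive.  An all-zero voxel gets R = 100 with
#' \code{degenerate = TRUE}.
#'
#' @param x either a coefficient matrix (k x \code{shNCoef(lmax)}) or a list
#'   of per-order matrices from [buildShardMatrices()].
#' @param lmax even maximum order (inferred when missing).
#' @param shellB optional shell b-values recorded in the result.
#' @return a [ShardDecomposition-class].
#' @examples
#' hbar <- kernelToZonal(stmKernel(), c(1000, 2000, 3000), lmax = 4)
#' coef <- convolveSH(hbar, shBasis(rbind(c(0, 0, 1)), 4)[1, ])
#' dec <- shardDecompose(coef)
#' powerRatio(dec)  # 100: one kernel, one ODF
#' @export
shardDecompose <- function(x, lmax = NULL, shellB = numeric()) {
  S <- if (is.list(x)) x else buildShardMatrices(x, lmax)
  if (is.null(lmax)) lmax <- 2L * (length(S) - 1L)
  k <- nrow(S[[1L]])
  if (!all(vapply(S, nrow, integer(1)) == k))
    stop("all per-order matrices must have the same number of shell rows")
  nComp <- max(vapply(S, function(m) min(dim(m)), integer(1)))
  sigmaL <- vector("list", length(S))
  u <- vector("list", length(S))
  v <- vector("list", length(S))
  s2 <- numeric(nComp)
  for (j in seq_along(S)) {
    sv <- svd(S[[j]])
    # sign convention: largest-|entry| of each left singular vector positive
    for (i in seq_along(sv$d)) {
      w <- which.max(abs(sv$u[, i]))
      if (sv$u[w, i] < 0) { sv$u[, i] <- -sv$u[, i]; sv$v[, i] <- -sv$v[, i] }
    }
    sigmaL[[j]] <- sv$d
    u[[j]] <- sv$u
    v[[j]] <- sv$v
    s2[seq_along(sv$d)] <- s2[seq_along(sv$d)] + sv$d^2
  }
  names(sigmaL) <- names(u) <- names(v) <- names(S)
  tot <- sum(s2)
  degenerate <- tot <= 0
  R <- if (degenerate) 100 else 100 * s2[1L] / tot
  new("ShardDecomposition", lmax = as.integer(lmax),
      shellB = as.numeric(shellB), sigmaL = sigmaL, u = u, v = v,
      sigma = sqrt(s2), R = R, degenerate = degenerate)
}

#' @describeIn ShardDecomposition pooled component effect sizes sigma_i.
#' @param object,dec a \code{ShardDecomposition}.
#' @export
pooledSigma <- function(dec) {
  stopifnot(is(dec, "ShardDecomposition"))
  dec@sigma
}

#' @describeIn ShardDecomposition percentage of signal power explained by
#'   the leading component.
#' @export
powerRatio <- function(dec) {
  stopifnot(is(dec, "ShardDecomposition"))
  dec@R
}

setMethod("show", "ShardDecomposition", function(object) {
  cat(sprintf("ShardDecomposition (lmax = %d, %d shells)\n",
              object@lmax, nrow(object@u[[1L]])))
  cat("  pooled effect sizes sigma_i:",
      paste(signif(object@sigma, 4), collapse = " "), "\n")
  cat(sprintf("  signal power explained R = %.3f%%%s\n", object@R,
              if (object@degenerate) " (degenerate all-zero voxel)" else ""))
})

# Rank-1 truncated coefficient matrix (k x shNCoef(lmax)).
rank1Coefficients <- function(dec) {
  lvals <- seq.int(0, dec@lmax, 2)
  k <- nrow(dec@u[[1L]])
  coef <- matrix(0, k, shNCoef(dec@lmax))
  for (j in seq_along(lvals)) {
    l <- lvals[j]
    cols <- shIndex(l, -l):shIndex(l, l)
    coef[, cols] <- dec@sigmaL[[j]][1L] *
      (dec@u[[j]][, 1L] %o% dec@v[[j]][, 1L])
  }
  coef
}

#' Rank-1 reconstruction and residuals
#'
#' Keeps only the leading component i = 1 of every per-order matrix, maps the
#' truncated coefficients back to signal space on the scheme's
#' diffusion-weighted directions, and returns the reconstruction yhat and the
#' residuals e = y - yhat.  Only the nu = k x directions-per-shell
#' diffusion-weighted measurements participate; b=0 volumes are carried
#' through untouched.
#'
#' @param dec a [ShardDecomposition-class] computed from \code{y} under the
#'   same scheme and lmax.
#' @param y the voxel's measurement vector ordered as the scheme.
#' @param scheme the [GradientScheme-class] used for the fit.
#' @param design optional precomputed design (internal fast path).
#' @return list of class \code{rank1Fit} with elements \code{yhat} and
#'   \code{resid} (numeric vectors of length nu, ordered shell by shell),
#'   \code{dwiIndex} (their positions in the scheme) and \code{coef} (the
#'   truncated coefficient matrix).
#' @export
rank1Reconstruct <- function(dec, y, scheme, design = NULL) {
  stopifnot(is(dec, "ShardDecomposition"))
  if (is.null(design)) design <- schemeDesign(scheme, dec@lmax)
  if (design$lmax != dec@lmax)
    stop(sprintf("decomposition lmax (%d) does not match design lmax (%d)",
                 dec@lmax, design$lmax))
  sch <- design$scheme
  if (nrow(dec@u[[1L]]) != design$k)
    stop("decomposition shell count does not match the scheme")
  if (length(y) != length(sch@bval))
    stop("signal length does not match the scheme")
  coef <- rank1Coefficients(dec)
  nu <- length(design$dwiIndex)
  yhat <- numeric(nu)
  for (b in seq_len(design$k))
    yhat[design$shellPos[[b]]] <- design$B[[b]] %*% coef[b, ]
  ydwi <- y[design$dwiIndex]
  structure(list(yhat = yhat, resid = ydwi - yhat,
                 dwiIndex = design$dwiIndex, coef = coef),
            class = "rank1Fit")
}
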