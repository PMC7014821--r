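# Real symmetric spherical harmonics (even orders only) and per-shell
# least-squares fitting.
#
# Convention (documented for interoperability; all internal quantities are
# convention-invariant): orthonormal real SH with the Condon-Shortley phase
# absorbed into the associated Legendre functions,
#   Y_{l,0}(theta,phi)  = Nbar_l^0 P_l(cos theta)
#   Y_{l,m}(theta,phi)  = sqrt(2) Nbar_l^m  P_l^m(cos theta) cos(m phi),  m > 0
#   Y_{l,-m}(theta,phi) = sqrt(2) Nbar_l^m  P_l^m(cos theta) sin(m phi),  m > 0
# with Nbar_l^m = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and P_l^m including
# (-1)^m.  Coefficients/columns are ordered (l ascending, m = -l..l).

#' Number of even-order SH basis functions
#'
#' @param lmax even maximum spherical-harmonic order.
#' @return (lmax+1)(lmax+2)/2, e.g. 45 for lmax = 8.
#' @export
shNCoef <- function(lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

# Normalized associated Legendre functions Pbar_l^m(x) for fixed m and
# l = m..lmax, such that Y_l^m = Pbar_l^m(cos theta) * {cos,sin}(m phi) basis
# is orthonormal.  Standard stable three-term recursion.
normLegendre <- function(x, lmax, m) {
  n <- length(x)
  out <- matrix(0, n, lmax - m + 1L)
  # Pbar_m^m
  pmm <- rep(sqrt(1 / (4 * pi)), n)
  if (m > 0) {
    s2 <- pmax(1 - x^2, 0)
    for (j in seq_len(m))
      pmm <- -pmm * sqrt((2 * j + 1) / (2 * j)) * sqrt(s2)
  } else {
    pmm <- pmm * sqrt(2 * m + 1)  # = sqrt(1/(4pi)) for m = 0
  }
  out[, 1L] <- pmm
  if (lmax > m) {
    pm1 <- x * sqrt(2 * m + 3) * pmm
    out[, 2L] <- pm1
    if (lmax > m + 1L) {
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        pl <- a * (x * pm1 - b * pmm)
        out[, l - m + 1L] <- pl
        pmm <- pm1
        pm1 <- pl
      }
    }
  }
  out
}

# Column index of (l, m) in the (l ascending, m ascending) even-order layout.
shIndex <- function(l, m) {
  as.integer(l * (l + 1) / 2 + m + 1L)
}

# b-values (s/mm^2) and diffusivities (um^2/ms) combine via b * D * 1e-3.
bUnit <- 1e-3

#' Evaluate the real symmetric spherical-harmonic basis
#'
#' Builds the design matrix of real, even-order spherical harmonics at a set
#' of unit directions, with columns ordered (l ascending, m = -l..l).  The
#' exact convention is documented in the package source header; the zonal
#' (m = 0) functions satisfy Y_l^0(z) = sqrt((2l+1)/(4 pi)).
#'
#' @param directions numeric matrix (n x 3) of unit vectors (renormalized
#'   when within 1e-3 of unit norm; rejected beyond that).
#' @param lmax even maximum order (default 8).
#' @return numeric matrix with n rows and \code{shNCoef(lmax)} columns.
#' @examples
#' B <- shBasis(rbind(c(0, 0, 1)), lmax = 4)
#' B[1, 1]  # 1 / (2 sqrt(pi))
#' @export
shBasis <- function(directions, lmax = 8L) {
  if (lmax %% 2 != 0)
    stop("lmax must be even: odd-order harmonics vanish for antipodally ",
         "symmetric dMRI signals")
  directions <- rbind(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("directions must be unit vectors (found norms off by > 1e-3); ",
         "normalize rows to unit length first")
  if (any(abs(nrm - 1) > 1e-6))
    directions <- directions / nrm
  x <- directions[, 3]                      # cos(theta)
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  B <- matrix(0, n, shNCoef(lmax))
  for (m in 0:lmax) {
    lseq <- seq.int(max(m, 2 * ceiling(m / 2)), lmax, by = 2L)
    lseq <- lseq[lseq >= m]
    if (!length(lseq)) next
    P <- normLegendre(x, lmax, m)
    if (m == 0) {
      for (l in lseq) B[, shIndex(l, 0L)] <- P[, l - m + 1L]
    } else {
      cm <- sqrt(2) * cos(m * phi)
      sm <- sqrt(2) * sin(m * phi)
      for (l in lseq) {
        B[, shIndex(l, m)] <- cm * P[, l - m + 1L]
        B[, shIndex(l, -m)] <- sm * P[, l - m + 1L]
      }
    }
  }
  B
}

# Precomputed per-shell design: basis, pseudoinverse, index bookkeeping.
# Internal; built once per (scheme, lmax) and threaded through voxel loops.
schemeDesign <- function(scheme, lmax = 8L) {
  stopifnot(is(scheme, "GradientScheme"))
  nc <- shNCoef(lmax)
  k <- length(scheme@shellB)
  if (k < 1L) stop("scheme has no diffusion-weighted shells")
  B <- vector("list", k)
  pinv <- vector("list", k)
  for (b in seq_len(k)) {
    idx <- scheme@shellIndex[[b]]
    if (length(idx) < nc)
      stop(sprintf(
        "shell %d (b = %g s/mm^2) has %d directions but the lmax = %d basis needs >= %d",
        b, scheme@shellB[b], length(idx), lmax, nc))
    Bb <- shBasis(scheme@dirs[idx, , drop = FALSE], lmax)
    qrB <- qr(Bb)
    if (qrB$rank < nc)
      stop(sprintf("shell %d design matrix is rank-deficient (%d < %d)",
                   b, qrB$rank, nc))
    B[[b]] <- Bb
    pinv[[b]] <- qr.solve(qrB, diag(length(idx)))
  }
  dwi <- unlist(scheme@shellIndex)
  # positions of each shell's measurements inside the DWI-only vector
  shellPos <- split(seq_along(dwi), rep(seq_len(k), lengths(scheme@shellIndex)))
  list(scheme = scheme, lmax = as.integer(lmax), nc = nc, k = k,
       B = B, pinv = pinv, dwiIndex = dwi, shellPos = shellPos,
       blockSizes = as.integer(2 * seq.int(0, lmax, 2) + 1))
}

#' Fit per-shell spherical-harmonic coefficients
#'
#' Ordinary least-squares fit of one voxel's measurements to the even-order
#' SH basis, shell by shell.  b=0 measurements never enter the fit; when
#' \code{normalizeB0} is TRUE the diffusion-weighted signal is divided by the
#' voxel's mean b=0 signal first.
#'
#' @param y numeric vector of measurements ordered as the scheme.
#' @param scheme a [GradientScheme-class].
#' @param lmax even maximum order (default 8).
#' @param normalizeB0 divide by mean b=0 signal before fitting (default
#'   FALSE).
#' @param design optional precomputed design (internal fast path).
#' @return numeric matrix (k shells x \code{shNCoef(lmax)}), rows named by
#'   shell b-value, columns ordered (l ascending, m ascending).
#' @export
fitShellSH <- function(y, scheme, lmax = 8L, normalizeB0 = FALSE,
                       design = NULL) {
  if (is.null(design)) design <- schemeDesign(scheme, lmax)
  sch <- design$scheme
  if (length(y) != length(sch@bval))
    stop(sprintf("signal has %d entries but the scheme has %d measurements",
                 length(y), length(sch@bval)))
  if (normalizeB0) {
    if (!length(sch@b0Index))
      stop("normalizeB0 = TRUE but the scheme has no b = 0 measurements")
    s0 <- mean(y[sch@b0Index])
    if (s0 <= 0) stop("mean b = 0 signal is not positive; cannot normalize")
    y <- y / s0
  }
  coef <- matrix(0, design$k, design$nc)
  for (b in seq_len(design$k))
    coef[b, ] <- design$pinv[[b]] %*% y[sch@shellIndex[[b]]]
  rownames(coef) <- format(sch@shellB)
  coef
}

#' Spherical convolution as per-coefficient multiplication
#'
#' In the SH basis, convolving an axially symmetric kernel with an ODF
#' reduces to s_{l,b}^m = sqrt(4 pi / (2l+1)) * hbar_{l,b} * p_l^m, where
#' hbar_{l,b} are the kernel's zonal SH coefficients per shell and p_l^m the
#' ODF coefficients.
#'
#' @param hbar numeric matrix (k shells x number of even orders) of zonal
#'   kernel coefficients, columns l = 0, 2, ..., lmax, as returned by
#'   [kernelToZonal()]; or a vector for a single shell.
#' @param odf numeric vector of ODF SH coefficients, length
#'   \code{shNCoef(lmax)}, ordered (l ascending, m ascending).
#' @return numeric matrix (k x \code{shNCoef(lmax)}) of per-shell signal SH
#'   coefficients.
#' @export
convolveSH <- function(hbar, odf) {
  hbar <- rbind(hbar)
  lmax <- 2L * (ncol(hbar) - 1L)
  if (length(odf) != shNCoef(lmax))
    stop(sprintf(
      "kernel (lmax = %d) and ODF (length %d) disagree: ODF must have %d coefficients",
      lmax, length(odf), shNCoef(lmax)))
  lvals <- seq.int(0, lmax, 2)
  scale <- sqrt(4 * pi / (2 * lvals + 1))
  out <- matrix(0, nrow(hbar), length(odf))
  for (j in seq_along(lvals)) {
    l <- lvals[j]
    cols <- shIndex(l, -l):shIndex(l, l)
    out[, cols] <- (scale[j] * hbar[, j]) %o% odf[cols]
  }
  out
}

# Product quadrature grid on the sphere, exact for band-limited integrands:
# Gauss-Legendre in cos(theta) x uniform trapezoid in phi.
sphereQuadrature <- function(nTheta = 64L, nPhi = 128L) {
  gl <- pracma::gaussLegendre(nTheta, -1, 1)
  phi <- 2 * pi * (seq_len(nPhi) - 1) / nPhi
  ct <- rep(gl$x, times = nPhi)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, each = nTheta)
  list(
    points = cbind(st * cos(ph), st * sin(ph), ct),
    weights = rep(gl$w, times = nPhi) * (2 * pi / nPhi)
  )
}
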