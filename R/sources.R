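# The source-extraction chain: pixelwise variance normalization after a
# first SVD pass, SVD/PCA, singular-spectrum shoulder detection (45-degree
# tangent on the normalized log spectrum), the double-the-shoulder rule,
# fixed-point spatial ICA, the map-sign convention, k-sigma ROI masks and
# weighted ROI time series.

#' Variance-normalize a movie
#'
#' A first SVD pass removes the top \code{nPresvd} components, the pixelwise
#' temporal variance of the residual is computed (no spatial filtering), and
#' the original data are divided voxelwise by its square root
#' (epsilon-floored). This equalizes the noise floor across voxels so that
#' the subsequent PCA is not dominated by bright regions.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param nPresvd number of leading SVD components removed before measuring
#'   the variance (must be below the matrix rank).
#' @param epsilon relative floor on the variance.
#' @return list with \code{volumes} (normalized \linkS4class{VolumeSeries}),
#'   \code{varianceMap} (3D array), and \code{nFloored} (voxels at the
#'   floor).
#' @export
varianceNormalize <- function(vs, nPresvd = 2, epsilon = 1e-8) {
  stopifnot(is(vs, "VolumeSeries"))
  X <- flattenVolumes(vs@data)
  nt <- ncol(X)
  if (nPresvd >= min(dim(X)))
    stop("nPresvd must be below min(voxels, frames)")
  R <- X
  if (nPresvd > 0) {
    Q <- .topTemporalSubspace(X, nPresvd)
    R <- X - (X %*% Q) %*% t(Q)
  }
  v <- rowMeans(R^2) - rowMeans(R)^2
  v <- v * nt / (nt - 1)
  vmax <- max(v)
  if (vmax <= 0) stop("zero variance everywhere: constant movie")
  floorVal <- epsilon * vmax
  flo <- v < floorVal
  sdv <- sqrt(pmax(v, floorVal))
  vs@data <- array(X / sdv, dim(vs@data))
  vs <- .stamp(vs, sprintf("variance normalized (presvd %d; %d floored)",
                           nPresvd, sum(flo)))
  list(volumes = vs, varianceMap = array(v, dim(vs@data)[1:3]),
       nFloored = sum(flo))
}

# orthonormal basis (frames x k) of the top-k right-singular subspace by
# blocked power iteration on the temporal side; deterministic
.topTemporalSubspace <- function(X, k, iters = 30, seed = 7L) {
  nt <- ncol(X)
  Q <- withSeed(seed, qr.Q(qr(matrix(stats::rnorm(nt * k), nt, k))))
  for (i in seq_len(iters)) {
    Z <- X %*% Q
    Q <- qr.Q(qr(crossprod(X, Z)))
  }
  Q
}

#' Thin SVD of a movie (PCA)
#'
#' Singular value decomposition of the voxels-by-frames matrix via the
#' smaller Gram matrix. All singular values are returned; the top \code{k}
#' spatial/temporal mode pairs are retained.
#'
#' @param vs a \linkS4class{VolumeSeries} (finite values, >= 2 frames).
#' @param k number of mode pairs to retain (default: all).
#' @return A \linkS4class{SingularSpectrum}.
#' @export
pcaVolumes <- function(vs, k = NULL) {
  stopifnot(is(vs, "VolumeSeries"))
  if (nFrames(vs) < 2) stop("need at least 2 frames")
  if (!all(is.finite(vs@data))) stop("non-finite values in data")
  X <- flattenVolumes(vs@data)
  if (is.null(k)) k <- min(dim(X))
  k <- min(k, dim(X))
  sp <- .thinSvd(X, k)
  new("SingularSpectrum", values = sp$d,
      spatialModes = sp$u, temporalModes = sp$v,
      spatialDim = dim(vs@data)[1:3])
}

#' Detect the shoulder of a singular value spectrum
#'
#' Both axes of the log spectrum are normalized to [0, 1] (index and log
#' singular value), making the "45-degree tangent" well defined; the function
#' returns the first index at which the centered finite-difference slope of
#' the normalized curve crosses -1. A spectrum whose slope never crosses -1
#' (e.g. flat) raises a "no shoulder" error; callers may fall back to a
#' fixed component count.
#'
#' @param spectrum a \linkS4class{SingularSpectrum} or a numeric vector of
#'   singular values (>= 4, strictly positive).
#' @return the shoulder index (1-based).
#' @export
detectShoulder <- function(spectrum) {
  sv <- if (is(spectrum, "SingularSpectrum")) spectrum@values else spectrum
  # numerical-rank zeros at the tail carry no shape information; drop them
  tiny <- sv <= max(sv) * 1e-12
  if (any(tiny)) sv <- sv[seq_len(which.max(tiny) - 1L)]
  if (length(sv) < 4) stop("need at least 4 singular values")
  if (any(sv <= 0)) stop("spectrum must be strictly positive")
  n <- length(sv)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- log(sv)
  rng <- max(y) - min(y)
  if (rng <= 0) stop("no shoulder: flat spectrum")
  y <- (y - min(y)) / rng
  # centered slopes at interior indices
  s <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  idx <- 2:(n - 1)
  if (s[1] == -1) return(idx[1])
  for (j in 2:length(s)) {
    if (s[j] == -1 || (s[j - 1] + 1) * (s[j] + 1) < 0) return(idx[j])
  }
  stop("no shoulder: normalized slope never crosses -1")
}

#' The double-the-shoulder rule for the component count
#'
#' Keeping twice the number of components at the spectrum shoulder retains
#' low-variance activity components while still discarding noise; the count
#' is clamped to the available rank.
#'
#' @param shoulder shoulder index (>= 1).
#' @param rank available rank (clamp).
#' @return integer component count.
#' @export
chooseNComponents <- function(shoulder, rank = Inf) {
  stopifnot(shoulder >= 1)
  as.integer(min(2 * shoulder, rank))
}

#' Spatial ICA on the leading SVD modes
#'
#' Fixed-point (FastICA-type) independent component analysis applied to the
#' top-n spatial SVD modes: the unmixed directions are spatial maps, made
#' maximally non-Gaussian under the logcosh contrast with symmetric
#' decorrelation. The component time series are the least-squares projection
#' of the rank-n data onto the unmixed maps, variance-normalized, with the
#' scale retained so that maps x (scale * traces) reconstructs the rank-n
#' truncation exactly. The spatial modes are mean-free by construction, so no
#' additional centering is applied. Deterministic given the seed.
#'
#' @param spectrum a \linkS4class{SingularSpectrum} retaining at least n
#'   modes.
#' @param n number of components to unmix.
#' @param seed integer seed for the unmixing initialization.
#' @param maxIter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing rotation.
#' @return A \linkS4class{ComponentSet}; \code{meta(cs)$converged} reports
#'   convergence, and non-convergence additionally raises a warning.
#' @export
runIca <- function(spectrum, n, seed = 1, maxIter = 500, tol = 1e-4) {
  stopifnot(is(spectrum, "SingularSpectrum"))
  kAvail <- ncol(spectrum@spatialModes)
  if (n > kAvail)
    stop("n exceeds the retained rank (", kAvail, ")")
  U <- spectrum@spatialModes[, seq_len(n), drop = FALSE]
  nv <- nrow(U)
  Z <- t(U) * sqrt(nv)    # n x voxels, exactly white (uncentered)
  W <- withSeed(seed, {
    W0 <- matrix(stats::rnorm(n * n), n, n)
    .symDecorrelate(W0)
  })
  converged <- FALSE
  iters <- maxIter
  for (it in seq_len(maxIter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gPrime <- rowMeans(1 - G^2)
    Wnew <- (G %*% t(Z)) / nv - gPrime * W
    Wnew <- .symDecorrelate(Wnew)
    delta <- max(abs(abs(diag(Wnew %*% t(W))) - 1))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; iters <- it; break }
  }
  if (!converged)
    warning("ICA did not converge in ", maxIter, " iterations")
  S <- W %*% Z            # n x voxels, unit-variance spatial maps
  # order components by decreasing captured variance of the rank-n data:
  # A = (1/sqrt(nv)) W D_n V_n^T  (exact least-squares trace, see below)
  Dn <- spectrum@values[seq_len(n)]
  Vn <- spectrum@temporalModes[, seq_len(n), drop = FALSE]
  A <- (W * rep(1 / sqrt(nv), n)) %*% (Dn * t(Vn))   # n x frames
  energy <- rowSums(A^2)
  ord <- order(energy, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[ord, , drop = FALSE]
  scale <- apply(A, 1, stats::sd)
  scale[scale == 0] <- 1
  traces <- t(A / scale)
  new("ComponentSet",
      maps = array(t(S), c(spectrum@spatialDim, n)),
      traces = traces, traceScale = scale, signFixed = FALSE,
      regionLabel = rep("unassigned", n),
      artifact = rep("activity", n),
      nRegionsPresent = rep(NA_integer_, n), nObjects = rep(NA_integer_, n),
      meta = list(converged = converged, iterations = iters, seed = seed,
                  contrast = "logcosh", tol = tol))
}

# symmetric decorrelation W <- (W W^T)^{-1/2} W
.symDecorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  K <- e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-30)))
  K %*% W
}

#' Apply the map-sign convention
#'
#' Each (map, trace) pair is flipped together so that the mean of the map's
#' positive side is at least as large as the absolute mean of its negative
#' side. Idempotent.
#'
#' @param cs a \linkS4class{ComponentSet}.
#' @return the sign-fixed \linkS4class{ComponentSet}.
#' @export
fixSigns <- function(cs) {
  stopifnot(is(cs, "ComponentSet"))
  M <- flattenVolumes(cs@maps)
  for (i in seq_len(ncol(M))) {
    m <- M[, i]
    pm <- if (any(m > 0)) mean(m[m > 0]) else 0
    nm <- if (any(m < 0)) abs(mean(m[m < 0])) else 0
    if (pm < nm) {
      M[, i] <- -m
      cs@traces[, i] <- -cs@traces[, i]
    }
  }
  cs@maps <- array(M, dim(cs@maps))
  cs@signFixed <- TRUE
  cs
}

#' k-sigma threshold ROI mask from a component map
#'
#' The map's standard deviation is computed about zero (ICA maps are
#' mean-free by construction) and every voxel below \code{k} times it is set
#' to zero; the surviving positive map values are the ROI weights.
#'
#' @param map 3D component map (more than one voxel).
#' @param k threshold in SD units (default 3).
#' @param component component index recorded in the mask.
#' @param aboutZero compute the SD about zero (default) or about the mean.
#' @return A \linkS4class{RoiMask}.
#' @export
zscoreThresholdMask <- function(map, k = 3, component = 1L,
                                aboutZero = TRUE) {
  stopifnot(length(dim(map)) == 3L, length(map) > 1)
  s <- if (aboutZero) sqrt(mean(map^2)) else stats::sd(map)
  if (s == 0) stop("zero standard deviation: empty map")
  w <- ifelse(map >= k * s, map, 0)
  w <- pmax(w, 0)
  if (sum(w) <= 0)
    stop("no voxel survives the ", k, "-sigma threshold")
  new("RoiMask", weights = array(w, dim(map)), component = as.integer(component),
      thresholdK = k)
}

#' Weighted ROI time series
#'
#' Per frame, the ROI-weight-weighted average of the dF/F movie:
#' \code{sum(w * F) / sum(w)}.
#'
#' @param vsDff a dF/F \linkS4class{VolumeSeries}.
#' @param mask a \linkS4class{RoiMask} on the same grid.
#' @return numeric time series (one value per frame).
#' @export
roiTimeseries <- function(vsDff, mask) {
  stopifnot(is(vsDff, "VolumeSeries"), is(mask, "RoiMask"))
  if (!all(dim(vsDff@data)[1:3] == dim(mask@weights)))
    stop("mask and movie grids differ")
  w <- as.numeric(mask@weights)
  as.numeric(crossprod(w, flattenVolumes(vsDff@data))) / sum(w)
}
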