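# Preprocessing chain: rigid motion correction, sign flip for voltage data,
# box-average detrending, first-order recursive (Kalman-style) denoising,
# SVD subtraction of movement components, dF/F, high-pass, behavior
# alignment, temporal concatenation and PSF-matched z-slab reduction.

#' Rigid motion correction by cross-correlation
#'
#' Aligns every frame to a reference volume (first frame or temporal mean) by
#' maximizing the spatial cross-correlation over integer shifts, refined to
#' subvoxel precision by a per-axis quadratic fit around the peak. Rigid
#' translation only; the estimated per-frame motion is returned alongside the
#' corrected movie.
#'
#' @param vs a \linkS4class{VolumeSeries} with at least 2 frames.
#' @param reference \code{"first"} or \code{"mean"}.
#' @param maxShiftVox largest |shift| searched per axis (voxels).
#' @return list with elements \code{volumes} (corrected
#'   \linkS4class{VolumeSeries}) and \code{motion}
#'   (\linkS4class{RigidMotion}).
#' @export
motionCorrect <- function(vs, reference = c("first", "mean"),
                          maxShiftVox = 5) {
  stopifnot(is(vs, "VolumeSeries"))
  reference <- match.arg(reference)
  d <- dim(vs@data)
  if (d[4] < 2) stop("need at least 2 frames")
  ref <- if (reference == "first") vs@data[, , , 1] else
    array(rowMeans(flattenVolumes(vs@data)), d[1:3])
  ref <- ref - mean(ref)
  refF <- Conj(fft(ref))
  # wrapped shift axes: entry k of the correlation corresponds to shift s
  axShift <- lapply(1:3, function(a) {
    s <- seq_len(d[a]) - 1L
    ifelse(s > d[a] / 2, s - d[a], s)
  })
  allowed <- lapply(1:3, function(a) abs(axShift[[a]]) <= maxShiftVox)
  trans <- matrix(0, d[4], 3)
  out <- vs@data
  warned <- FALSE
  for (t in seq_len(d[4])) {
    fr <- vs@data[, , , t]
    if (stats::sd(fr) == 0) {
      if (!warned) {
        warning("constant frame(s): zero shift assumed")
        warned <- TRUE
      }
      next
    }
    cc <- Re(fft(refF * fft(fr - mean(fr)), inverse = TRUE))
    ccA <- cc
    ccA[!allowed[[1]], , ] <- -Inf
    ccA[, !allowed[[2]], ] <- -Inf
    ccA[, , !allowed[[3]]] <- -Inf
    pk <- which(ccA == max(ccA), arr.ind = TRUE)[1, ]
    est <- numeric(3)
    for (a in 1:3) {
      i0 <- pk[a]
      est[a] <- axShift[[a]][i0]
      im <- if (i0 == 1L) d[a] else i0 - 1L
      ip <- if (i0 == d[a]) 1L else i0 + 1L
      idx <- as.list(pk)
      idx[[a]] <- c(im, i0, ip)
      v <- cc[idx[[1]], idx[[2]], idx[[3]]]
      denom <- v[1] - 2 * v[2] + v[3]
      if (is.finite(denom) && abs(denom) > 1e-12) {
        delta <- 0.5 * (v[1] - v[3]) / denom
        est[a] <- est[a] + max(min(delta, 0.5), -0.5)
      }
    }
    trans[t, ] <- est
    if (any(est != 0)) out[, , , t] <- shift3d(fr, -est)
  }
  motion <- new("RigidMotion", translation = trans,
                rotation = matrix(0, 0, 3))
  vs@data <- out
  list(volumes = .stamp(vs, sprintf("motion corrected (ref %s)", reference)),
       motion = motion)
}

#' Flip the sign of a voltage movie
#'
#' ArcLight fluorescence decreases with depolarization, so voltage time
#' series are multiplied by -1 before analysis. Applying the operation twice
#' restores the input exactly.
#'
#' @param vs a \linkS4class{VolumeSeries} with probe \code{"arclight"}.
#' @param force allow flipping other probes.
#' @return the negated \linkS4class{VolumeSeries}.
#' @export
invertSign <- function(vs, force = FALSE) {
  stopifnot(is(vs, "VolumeSeries"))
  if (vs@probe != "arclight" && !force)
    stop("sign inversion is meant for arclight data (probe is '", vs@probe,
         "'); use force = TRUE to override")
  vs@data <- -vs@data
  .stamp(vs, "sign inverted")
}

#' Remove slow trends by subtracting a running box average
#'
#' Per voxel, subtracts a centered moving box average (window 15-30 s
#' typically) to remove background fluorescence and the photobleaching decay.
#' Edges use shrinking (truncated) windows; even window lengths use the
#' standard centered even-order moving average (half weights at the two
#' extreme frames), so a linear ramp is removed exactly at interior frames.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param windowS box window length in seconds (>= 3 frames at the movie's
#'   rate; at most the recording length).
#' @return detrended \linkS4class{VolumeSeries}.
#' @export
detrend <- function(vs, windowS = 30) {
  stopifnot(is(vs, "VolumeSeries"))
  w <- round(windowS * vs@frameRate)
  nt <- nFrames(vs)
  if (w < 3) stop("window must span at least 3 frames")
  if (w > nt) stop("window (", w, " frames) longer than the recording (",
                   nt, " frames)")
  X <- flattenVolumes(vs@data)
  vs@data <- array(X - boxMeanTime(X, w), dim(vs@data))
  .stamp(vs, sprintf("detrended (box %g s = %d frames)", windowS, w))
}

#' First-order recursive temporal denoising
#'
#' Per-voxel causal filter \code{est[t] = (1 - g) * est[t-1] + g * obs[t]}
#' with \code{est[1] = obs[1]} — the steady-state (fixed-gain) form of a
#' scalar Kalman filter. Gain 1 is the identity.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param gain filter gain in (0, 1].
#' @return denoised \linkS4class{VolumeSeries}.
#' @export
kalmanDenoise <- function(vs, gain = 0.5) {
  stopifnot(is(vs, "VolumeSeries"))
  if (gain <= 0 || gain > 1) stop("gain must lie in (0, 1]")
  if (gain == 1) return(.stamp(vs, "kalman denoised (gain 1)"))
  X <- flattenVolumes(vs@data)
  for (t in 2:ncol(X))
    X[, t] <- (1 - gain) * X[, t - 1] + gain * X[, t]
  vs@data <- array(X, dim(vs@data))
  .stamp(vs, sprintf("kalman denoised (gain %g)", gain))
}

#' Subtract movement-related SVD components
#'
#' Removes selected rank-1 (spatial x temporal) SVD terms from the movie.
#' In \code{"auto"} mode, components whose spatial map energy concentrates on
#' high-gradient voxels (shadow-like maps hugging intensity edges, the
#' signature of residual movement) are flagged and removed.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param components integer vector of rank positions to remove, or
#'   \code{"auto"}.
#' @param nAuto number of leading components examined in auto mode.
#' @param edgeFraction auto mode: flag a component when more than this
#'   fraction of its map energy sits on the top-quartile-gradient voxels.
#' @return list with \code{volumes} (cleaned movie) and \code{removed}
#'   (indices removed).
#' @export
svdMotionRemoval <- function(vs, components = "auto", nAuto = 10,
                             edgeFraction = 0.5) {
  stopifnot(is(vs, "VolumeSeries"))
  if (length(vs@data) == 0) stop("empty data")
  X <- flattenVolumes(vs@data)
  if (identical(components, "auto")) {
    sp <- .thinSvd(X, min(nAuto, dim(X) - 1))
    meanVol <- array(rowMeans(X), dim(vs@data)[1:3])
    gmag <- .gradMag(meanVol)
    edge <- gmag >= stats::quantile(gmag, 0.75)
    components <- which(vapply(seq_len(ncol(sp$u)), function(i) {
      e <- sp$u[, i]^2
      sum(e[edge]) / sum(e) > edgeFraction
    }, logical(1)))
    if (!length(components))
      return(list(volumes = .stamp(vs, "svd motion removal (none flagged)"),
                  removed = integer(0)))
    u <- sp$u; dvals <- sp$d; v <- sp$v
  } else {
    components <- as.integer(components)
    if (!length(components))
      return(list(volumes = vs, removed = integer(0)))
    k <- max(components)
    if (k > min(dim(X))) stop("component index exceeds available rank")
    sp <- .thinSvd(X, k)
    u <- sp$u; dvals <- sp$d; v <- sp$v
  }
  for (i in components)
    X <- X - dvals[i] * u[, i, drop = FALSE] %*% t(v[, i, drop = FALSE])
  vs@data <- array(X, dim(vs@data))
  list(volumes = .stamp(vs, sprintf("svd motion removal (components %s)",
                                    paste(components, collapse = ","))),
       removed = components)
}

# thin SVD of a voxels x frames matrix; exact LAPACK SVD for small inputs,
# the smaller Gram matrix for large movies (where the ~sqrt(eps) value
# accuracy is immaterial). Returns top-k u (voxels x k), d (all values),
# v (frames x k).
.thinSvd <- function(X, k) {
  nv <- nrow(X); nt <- ncol(X)
  k <- min(k, nv, nt)
  if (length(X) <= 4e6) {
    s <- svd(X, nu = k, nv = k)
    return(list(u = s$u, d = s$d, v = s$v))
  }
  if (nt <= nv) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    dAll <- sqrt(pmax(e$values, 0))
    v <- e$vectors[, seq_len(k), drop = FALSE]
    dk <- dAll[seq_len(k)]
    u <- X %*% v
    pos <- dk > max(dAll[1], .Machine$double.eps) * 1e-12
    u[, pos] <- sweep(u[, pos, drop = FALSE], 2, dk[pos], "/")
    list(u = u, d = dAll, v = v)
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    dAll <- sqrt(pmax(e$values, 0))
    u <- e$vectors[, seq_len(k), drop = FALSE]
    dk <- dAll[seq_len(k)]
    v <- crossprod(X, u)
    pos <- dk > max(dAll[1], .Machine$double.eps) * 1e-12
    v[, pos] <- sweep(v[, pos, drop = FALSE], 2, dk[pos], "/")
    list(u = u, d = dAll, v = v)
  }
}

# central-difference gradient magnitude of a 3D field
.gradMag <- function(vol) {
  d <- dim(vol)
  g <- array(0, d)
  for (a in 1:3) {
    ip <- pmin(seq_len(d[a]) + 1L, d[a])
    im <- pmax(seq_len(d[a]) - 1L, 1L)
    idxP <- idxM <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idxP[[a]] <- ip; idxM[[a]] <- im
    g <- g + (vol[idxP[[1]], idxP[[2]], idxP[[3]]] -
                vol[idxM[[1]], idxM[[2]], idxM[[3]]])^2
  }
  sqrt(g)
}

#' Fractional fluorescence change (dF/F)
#'
#' Per voxel, \code{(F - F0) / F0} with the baseline F0 taken as the temporal
#' mean or a percentile. Voxels whose baseline is not strictly positive after
#' epsilon flooring are masked (set to zero) and their count reported.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param baseline \code{"mean"} or \code{"percentile"}.
#' @param percentile percentile (0-100) used when \code{baseline =
#'   "percentile"}.
#' @param epsilon floor for the baseline, relative to its maximum.
#' @return dF/F \linkS4class{VolumeSeries}.
#' @export
dff <- function(vs, baseline = c("mean", "percentile"), percentile = 10,
                epsilon = 1e-6) {
  stopifnot(is(vs, "VolumeSeries"))
  baseline <- match.arg(baseline)
  X <- flattenVolumes(vs@data)
  f0 <- if (baseline == "mean") rowMeans(X)
  else apply(X, 1, stats::quantile, probs = percentile / 100, names = FALSE)
  floorVal <- epsilon * max(abs(f0))
  bad <- f0 <= floorVal
  if (any(bad))
    message(sum(bad), " voxel(s) masked: baseline not strictly positive")
  f0[bad] <- 1
  X <- sweep(X, 1, f0, "/") - 1
  X[bad, ] <- 0
  vs@data <- array(X, dim(vs@data))
  .stamp(vs, sprintf("dF/F (baseline %s%s; %d masked)", baseline,
                     if (baseline == "percentile")
                       sprintf(" p%g", percentile) else "",
                     sum(bad)))
}

#' High-pass by smoothed subtraction
#'
#' Subtracts the movie smoothed with a centered box average (default 100 ms),
#' keeping only activity faster than the window.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param windowS smoothing window (s); must span at least 2 frames.
#' @return high-passed \linkS4class{VolumeSeries}.
#' @export
highpass <- function(vs, windowS = 0.1) {
  stopifnot(is(vs, "VolumeSeries"))
  w <- round(windowS * vs@frameRate)
  if (w < 2) stop("frame rate too low: window spans fewer than 2 frames")
  if (w > nFrames(vs)) stop("window longer than the recording")
  X <- flattenVolumes(vs@data)
  vs@data <- array(X - boxMeanTime(X, w), dim(vs@data))
  .stamp(vs, sprintf("highpass (box %g s = %d frames)", windowS, w))
}

#' Align a behavior trace to the fluorescence frame grid
#'
#' Corrects the linear clock drift between the behavior and fluorescence
#' cameras (about 30 ms per minute), then resamples the behavior onto the
#' fluorescence frame grid: nearest neighbor for the categorical state,
#' linear interpolation for the optic flow.
#'
#' @param behavior a \linkS4class{BehaviorTrace}.
#' @param fluorFrames number of fluorescence frames.
#' @param fluorRateHz fluorescence frame rate (Hz).
#' @param driftMsPerMin behavior clock drift, ms per minute (positive =
#'   behavior clock runs slow). |drift| above 10% of real time is rejected.
#' @return a \linkS4class{BehaviorTrace} on the fluorescence grid.
#' @export
alignBehavior <- function(behavior, fluorFrames, fluorRateHz,
                          driftMsPerMin = 30) {
  stopifnot(is(behavior, "BehaviorTrace"), fluorFrames > 0, fluorRateHz > 0)
  drift <- driftMsPerMin / 1000 / 60
  if (abs(drift) > 0.1) stop("drift magnitude above 10%: implausible")
  nb <- nFrames(behavior)
  # behavior sample i occurs at true time (i-1)/rb * (1 + drift)
  tf <- (seq_len(fluorFrames) - 1) / fluorRateHz
  bIdx <- tf / (1 + drift) * behavior@frameRate + 1
  bIdx <- pmin(pmax(bIdx, 1), nb)
  nearest <- pmin(pmax(round(bIdx), 1L), nb)
  lo <- floor(bIdx); hi <- pmin(lo + 1, nb); fr <- bIdx - lo
  lerp <- function(v) v[lo] * (1 - fr) + v[hi] * fr
  flowL <- lerp(behavior@flowLeft)
  flowR <- lerp(behavior@flowRight)
  # interpolation across a turn boundary may make both sides nonzero for one
  # frame; keep the dominant side so turns stay one-sided
  both <- flowL > 0 & flowR > 0
  flowL[both & flowR >= flowL] <- 0
  flowR[both & flowL > flowR] <- 0
  new("BehaviorTrace", frameRate = fluorRateHz,
      state = behavior@state[nearest], flowLeft = flowL, flowRight = flowR)
}

#' Concatenate movies in time
#'
#' @param vsList list of \linkS4class{VolumeSeries} with identical spatial
#'   dims, voxel size, frame rate and probe.
#' @return concatenated \linkS4class{VolumeSeries}; the provenance records
#'   the segment boundaries.
#' @export
concatVolumes <- function(vsList) {
  stopifnot(length(vsList) >= 1)
  ref <- vsList[[1]]
  for (v in vsList[-1]) {
    if (!all(dim(v@data)[1:3] == dim(ref@data)[1:3]))
      stop("mismatched field: spatial dimensions")
    if (!all(v@voxelSize == ref@voxelSize))
      stop("mismatched field: voxelSize")
    if (v@frameRate != ref@frameRate) stop("mismatched field: frameRate")
    if (v@probe != ref@probe) stop("mismatched field: probe")
  }
  if (length(vsList) == 1) return(ref)
  counts <- vapply(vsList, nFrames, numeric(1))
  dat <- array(unlist(lapply(vsList, function(v) v@data), use.names = FALSE),
               c(dim(ref@data)[1:3], sum(counts)))
  ref@data <- dat
  .stamp(ref, sprintf("concatenated (boundaries at %s)",
                      paste(cumsum(counts)[-length(counts)], collapse = ",")))
}

#' Reduce z dimensionality into PSF-matched slabs
#'
#' Partitions the z axis into contiguous slabs whose thickness tracks the
#' axial PSF height at that depth (greedy, outward from the depth of minimal
#' PSF height, i.e. the focal plane) and replaces each slab by its mean.
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param psfHeightProfile axial PSF FWHM per z layer: numeric vector of
#'   length \code{dim(vs)[3]} (um), or a function of signed depth (um).
#' @return z-reduced \linkS4class{VolumeSeries}; slab boundaries are recorded
#'   in the provenance and in attribute \code{"slabs"} of the returned data.
#' @export
zslabReduce <- function(vs, psfHeightProfile) {
  stopifnot(is(vs, "VolumeSeries"))
  d <- dim(vs@data)
  nz <- d[3]
  dz <- vs@voxelSize[3]
  prof <- if (is.function(psfHeightProfile)) {
    depth <- (seq_len(nz) - (nz + 1) / 2) * dz
    psfHeightProfile(depth)
  } else as.numeric(psfHeightProfile)
  if (length(prof) != nz)
    stop("profile must give one PSF height per z layer")
  if (any(prof <= 0)) stop("profile must be positive")
  thick <- function(z) max(1L, min(nz, as.integer(round(prof[z] / dz))))
  focal <- which.min(prof)
  # greedy outward partition: up from the focal layer, then down
  slabs <- list()
  z <- focal
  while (z <= nz) {
    t <- thick(z)
    slabs <- c(slabs, list(z:min(nz, z + t - 1L)))
    z <- z + t
  }
  z <- focal - 1L
  down <- list()
  while (z >= 1L) {
    t <- thick(z)
    down <- c(down, list(max(1L, z - t + 1L):z))
    z <- z - t
  }
  slabs <- c(rev(down), slabs)
  if (!length(slabs)) stop("profile yields zero slabs")
  out <- array(0, c(d[1], d[2], length(slabs), d[4]))
  for (i in seq_along(slabs)) {
    sl <- slabs[[i]]
    out[, , i, ] <- if (length(sl) == 1) vs@data[, , sl, ]
    else apply(vs@data[, , sl, , drop = FALSE], c(1, 2, 4), mean)
  }
  bounds <- vapply(slabs, function(s) s[1], integer(1))
  vs@data <- out
  attr(vs@data, "slabs") <- slabs
  .stamp(vs, sprintf("z-slab reduced (%d slabs, starts %s)", length(slabs),
                     paste(bounds, collapse = ",")))
}
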