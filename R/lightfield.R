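# Toy light field forward model, Richardson-Lucy volumetric deconvolution,
# and bead-based PSF characterization. The forward model is a geometric-optics
# approximation: each reconstruction depth is blurred by a normalized lateral
# Gaussian that widens away from the focal plane, then projected to the sensor
# with a depth-proportional subaperture (parallax) offset. Circular boundary
# handling makes the adjoint exact, which is the correctness core of RL.

#' Build a depth-indexed PSF library
#'
#' The default geometry is the standard reconstruction stack: 40 layers at
#' 6 um spacing. The kernel at signed depth d is a normalized lateral
#' Gaussian with sigma(d) = sigma0 * (1 + wideningRate * |d|). The defaults
#' reproduce a lateral FWHM growing from ~3.5 um at focus to ~12 um at the
#' stack edge.
#'
#' @param nLayers number of reconstruction depths (>= 1).
#' @param layerSpacingUm axial spacing between depths (um).
#' @param focalWidthUm lateral Gaussian sigma at the focal plane (um).
#' @param wideningRate fractional sigma growth per um of |depth|.
#' @param voxelSize voxel pitch (um), length 3.
#' @return A \linkS4class{PSFLibrary}.
#' @export
buildPsfLibrary <- function(nLayers = 40, layerSpacingUm = 6,
                            focalWidthUm = 1.49, wideningRate = 0.02,
                            voxelSize = c(3, 3, 6)) {
  if (nLayers < 1) stop("nLayers must be >= 1")
  if (layerSpacingUm <= 0 || focalWidthUm <= 0)
    stop("widths and spacings must be positive")
  if (wideningRate < 0) stop("wideningRate must be >= 0")
  depths <- (seq_len(nLayers) - (nLayers + 1) / 2) * layerSpacingUm
  sigUm <- focalWidthUm * (1 + wideningRate * abs(depths))
  dx <- voxelSize[1]
  kernels <- lapply(sigUm, function(s) {
    sp <- s / dx
    r <- max(1L, ceiling(3 * sp))
    ax <- (-r):r
    k <- exp(-outer(ax^2, ax^2, "+") / (2 * sp^2))
    k / sum(k)
  })
  new("PSFLibrary", depths = depths, kernels = kernels, sigmaLat = sigUm,
      voxelSize = as.numeric(voxelSize))
}

# per-depth parallax offset in sensor pixels (nearest-pixel rounded):
# proportional to depth, spanning +/- lensletPitch/2 across the stack.
# Each depth projects as a subaperture pair (+offset and -offset) with
# unequal view weights, so the stamp separation encodes |depth| and the
# weight asymmetry its sign, as the opposing views of a real lenslet do.
.viewWeights <- c(0.6, 0.4)

.disparities <- function(psf, lensletPitchPx) {
  mx <- max(abs(psf@depths))
  if (mx == 0) return(rep(0L, length(psf@depths)))
  as.integer(round(psf@depths / mx * lensletPitchPx / 2))
}

#' Project a volume to a 2D light field sensor image
#'
#' Linear nonnegative forward operator: each depth layer is blurred by its
#' kernel and rolled by its depth-proportional parallax offset, then all
#' depths are summed onto the sensor.
#'
#' @param volume nonnegative 3D array; the z extent must match the PSF depth
#'   count, and the lateral dims must be divisible by the lenslet pitch.
#' @param psf a \linkS4class{PSFLibrary}.
#' @param lensletPitchPx microlens pitch in sensor pixels.
#' @return 2D sensor image.
#' @export
forwardProject <- function(volume, psf, lensletPitchPx = 4L) {
  stopifnot(is(psf, "PSFLibrary"), length(dim(volume)) == 3L)
  d <- dim(volume)
  if (d[3] != length(psf@depths))
    stop("volume z dimension (", d[3], ") must match PSF depth count (",
         length(psf@depths), ")")
  if (any(d[1:2] %% lensletPitchPx != 0))
    stop("lateral dims must be divisible by the lenslet pitch")
  if (any(volume < 0)) stop("volume must be nonnegative")
  disp <- .disparities(psf, lensletPitchPx)
  img <- matrix(0, d[1], d[2])
  for (z in seq_len(d[3])) {
    kf <- fft(kernelFFT(psf@kernels[[z]], d[1:2]))
    bl <- conv2circ(volume[, , z], kf)
    img <- img + .viewWeights[1] * roll2d(bl, disp[z], 0L) +
      .viewWeights[2] * roll2d(bl, -disp[z], 0L)
  }
  pmax(img, 0)   # clip FFT round-off
}

#' Adjoint of the light field forward projection
#'
#' @param image 2D sensor image.
#' @param psf a \linkS4class{PSFLibrary}.
#' @param lensletPitchPx microlens pitch in sensor pixels.
#' @return 3D volume (the transpose operator applied to \code{image}).
#' @export
adjointProject <- function(image, psf, lensletPitchPx = 4L) {
  stopifnot(is(psf, "PSFLibrary"), length(dim(image)) == 2L)
  d <- dim(image)
  nz <- length(psf@depths)
  disp <- .disparities(psf, lensletPitchPx)
  vol <- array(0, c(d, nz))
  for (z in seq_len(nz)) {
    kf <- fft(kernelFFT(psf@kernels[[z]], d))
    # adjoint of (roll o conv): conv with the (symmetric) kernel, reverse roll
    vol[, , z] <- conv2circ(.viewWeights[1] * roll2d(image, -disp[z], 0L) +
                              .viewWeights[2] * roll2d(image, disp[z], 0L),
                            kf)
  }
  vol
}

#' Richardson-Lucy volumetric deconvolution
#'
#' Multiplicative RL iteration with the light field forward operator and its
#' adjoint. Predicted intensities are floored at 1e-12 so division is always
#' defined; every iterate is nonnegative. The lateral reconstruction sampling
#' can be coarsened by an integer factor of the PSF's native pitch (e.g. 6 um
#' instead of 3 um) by binning the sensor frames.
#'
#' @param frames a \linkS4class{LightFieldSeries}.
#' @param psf a \linkS4class{PSFLibrary}.
#' @param nIter number of RL iterations (>= 1).
#' @param lateralSamplingUm lateral sampling of the reconstruction; must be
#'   an integer multiple of the PSF voxel pitch.
#' @return A \linkS4class{VolumeSeries} of reconstructed volumes.
#' @export
deconvolve <- function(frames, psf, nIter = 30, lateralSamplingUm = NULL) {
  stopifnot(is(frames, "LightFieldSeries"), is(psf, "PSFLibrary"))
  if (nIter < 1) stop("nIter must be >= 1")
  dx <- psf@voxelSize[1]
  if (is.null(lateralSamplingUm)) lateralSamplingUm <- dx
  f <- lateralSamplingUm / dx
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("lateralSamplingUm must be an integer multiple of the PSF pitch")
  f <- as.integer(round(f))
  fr <- frames@frames
  pitch <- frames@lensletPitch
  if (f > 1) {
    fr <- binFrames(fr, f)
    pitch <- max(1L, pitch %/% f)
    # same sigma profile in um, kernels resampled at the coarser pitch
    kernels <- lapply(psf@sigmaLat, function(s) {
      sp <- s / lateralSamplingUm
      r <- max(1L, ceiling(3 * sp))
      ax <- (-r):r
      k <- exp(-outer(ax^2, ax^2, "+") / (2 * sp^2))
      k / sum(k)
    })
    psf <- new("PSFLibrary", depths = psf@depths, kernels = kernels,
               sigmaLat = psf@sigmaLat,
               voxelSize = c(lateralSamplingUm, lateralSamplingUm,
                             psf@voxelSize[3]))
  }
  d <- dim(fr)
  nz <- length(psf@depths)
  nt <- d[3]
  eps <- 1e-12
  ones <- adjointProject(matrix(1, d[1], d[2]), psf, pitch)
  ones <- pmax(ones, eps)
  out <- array(0, c(d[1], d[2], nz, nt))
  for (t in seq_len(nt)) {
    y <- fr[, , t]
    x <- array(mean(y), c(d[1], d[2], nz))
    for (it in seq_len(nIter)) {
      pred <- forwardProject(x, psf, pitch)
      ratio <- y / pmax(pred, eps)
      x <- x * adjointProject(ratio, psf, pitch) / ones
      x <- pmax(x, 0)
    }
    out[, , , t] <- x
  }
  VolumeSeries(out,
               voxelSize = c(psf@voxelSize[1], psf@voxelSize[2],
                             if (nz > 1) diff(psf@depths)[1] else psf@voxelSize[3]),
               frameRate = frames@frameRate, probe = "gfp",
               provenance = sprintf("RL deconvolution (%d iterations)", nIter))
}

# integer-factor lateral binning (mean) of a (px, py, t) stack
binFrames <- function(fr, f) {
  d <- dim(fr)
  if (any(d[1:2] %% f != 0)) stop("frame dims not divisible by binning factor")
  nx <- d[1] %/% f; ny <- d[2] %/% f
  out <- array(0, c(nx, ny, d[3]))
  for (i in seq_len(f)) for (j in seq_len(f))
    out <- out + fr[seq(i, d[1], by = f), seq(j, d[2], by = f), , drop = FALSE]
  out / f^2
}

# 1D FWHM around a peak index by linear interpolation of the half-max
# crossings; returns width in samples, or NA (flagged) if a side never falls
# below half max.
.fwhm1d <- function(p, center) {
  peak <- p[center]
  if (peak <= 0) return(NA_real_)
  half <- peak / 2
  right <- NA_real_
  if (center < length(p)) {
    for (j in (center + 1):length(p)) {
      if (p[j] < half) {
        right <- (j - 1 - center) + (p[j - 1] - half) / (p[j - 1] - p[j])
        break
      }
    }
  }
  left <- NA_real_
  if (center > 1) {
    for (j in (center - 1):1) {
      if (p[j] < half) {
        left <- (center - j - 1) + (p[j + 1] - half) / (p[j + 1] - p[j])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  left + right
}

#' Measure lateral and axial FWHM of beads in a reconstructed volume
#'
#' For each bead center, takes 1D intensity profiles through the center along
#' x, y and z, finds the half-maximum crossings by linear interpolation, and
#' reports the lateral FWHM (mean of x and y) and axial FWHM (z) in
#' micrometers, grouped by signed depth from the middle plane. Profiles that
#' never fall below half max within the volume are flagged (NA width) rather
#' than silently truncated.
#'
#' @param beadVolume 3D reconstructed field.
#' @param beadCenters integer matrix (n x 3) of voxel coordinates.
#' @param voxelSize voxel pitch (um).
#' @return data.frame with columns depth_um, lateral_fwhm_um, axial_fwhm_um,
#'   flagged.
#' @export
measurePsfFwhm <- function(beadVolume, beadCenters, voxelSize = c(3, 3, 6)) {
  stopifnot(length(dim(beadVolume)) == 3L)
  beadCenters <- matrix(as.integer(beadCenters), ncol = 3)
  d <- dim(beadVolume)
  zMid <- (d[3] + 1) / 2
  rows <- lapply(seq_len(nrow(beadCenters)), function(i) {
    c0 <- beadCenters[i, ]
    if (any(c0 < 1) || any(c0 > d))
      stop("bead center outside the volume")
    fx <- .fwhm1d(beadVolume[, c0[2], c0[3]], c0[1]) * voxelSize[1]
    fy <- .fwhm1d(beadVolume[c0[1], , c0[3]], c0[2]) * voxelSize[2]
    fz <- .fwhm1d(beadVolume[c0[1], c0[2], ], c0[3]) * voxelSize[3]
    data.frame(depth_um = (c0[3] - zMid) * voxelSize[3],
               lateral_fwhm_um = mean(c(fx, fy)),
               axial_fwhm_um = fz,
               flagged = anyNA(c(fx, fy, fz)))
  })
  out <- do.call(rbind, rows)
  out[order(out$depth_um), , drop = FALSE]
}
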