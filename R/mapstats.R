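# Voxelwise condition and stimulus-response maps, indicator impulse-response
# kernels and regressors, and component/behavior statistics.

.kernelDefaults <- list(
  gcamp6f = list(rise = 0.15, decay = 0.6),
  gcamp6s = list(rise = 0.55, decay = 1.8),
  arclight = list(rise = 0.10, decay = 0.3)
)

#' Build an indicator impulse-response kernel
#'
#' Double-exponential impulse response \code{(1 - exp(-t/tau_r)) *
#' exp(-t/tau_d)}, with the rise constant solved so the peak sits at the
#' indicator's rise-to-peak time (0.15 s for GCaMP6f, 0.10 s for ArcLight,
#' 0.55 s for GCaMP6s). Peak-normalized and truncated once the tail falls
#' below 1e-3 of the peak.
#'
#' @param probe gcamp6f, gcamp6s or arclight.
#' @param frameRateHz sampling rate; must place at least 2 taps before the
#'   peak.
#' @param decayS decay time constant in seconds (default per probe).
#' @param riseToPeakS time to peak in seconds (default per probe).
#' @return A \linkS4class{Kernel}.
#' @examples
#' k <- makeKernel("gcamp6f", 100)
#' which.max(kernelTaps(k))   # peak at 0.15 s
#' @export
makeKernel <- function(probe = c("gcamp6f", "gcamp6s", "arclight"),
                       frameRateHz, decayS = NULL, riseToPeakS = NULL) {
  probe <- match.arg(probe)
  def <- .kernelDefaults[[probe]]
  if (is.null(decayS)) decayS <- def$decay
  if (is.null(riseToPeakS)) riseToPeakS <- def$rise
  if (decayS <= 0) stop("decayS must be > 0")
  if (frameRateHz * riseToPeakS < 2)
    stop("frame rate too low to sample the rise (need >= 2 taps before peak)")
  # peak time of (1 - e^{-t/a}) e^{-t/b} is a * log(1 + b/a); solve for a
  peakTime <- function(a) a * log(1 + decayS / a)
  tauR <- stats::uniroot(function(a) peakTime(a) - riseToPeakS,
                         interval = c(1e-6, 10 * decayS + 10),
                         tol = 1e-10)$root
  dt <- 1 / frameRateHz
  tMax <- riseToPeakS + decayS * log(1e4)   # generous tail before truncation
  tt <- seq(0, tMax, by = dt)
  h <- (1 - exp(-tt / tauR)) * exp(-tt / decayS)
  h <- h / max(h)
  keep <- max(which(h >= 1e-3))
  new("Kernel", taps = h[seq_len(keep)], riseToPeak = riseToPeakS,
      frameRate = frameRateHz, probe = probe)
}

# causal discrete convolution, output length = input length
convolveCausal <- function(x, taps) {
  n <- length(x)
  stats::convolve(x, rev(taps), type = "open")[seq_len(n)]
}

#' Convolve a behavior trace with an indicator kernel
#'
#' Causal discrete convolution of a per-frame scalar trace (e.g. ball optic
#' flow toward one side) with the indicator impulse response, producing a
#' regressor on the fluorescence timescale. Output length equals the input
#' length.
#'
#' @param trace per-frame scalar driver.
#' @param kernel a \linkS4class{Kernel}.
#' @param frameRateHz sampling rate of \code{trace}; must match the kernel's.
#' @return numeric regressor, same length as \code{trace}.
#' @export
buildRegressor <- function(trace, kernel, frameRateHz = kernel@frameRate) {
  stopifnot(is(kernel, "Kernel"))
  if (abs(frameRateHz - kernel@frameRate) > 1e-9)
    stop("trace frame rate (", frameRateHz, " Hz) does not match kernel (",
         kernel@frameRate, " Hz)")
  convolveCausal(as.numeric(trace), kernel@taps)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric series (length >= 3, non-constant).
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)
}

#' Squared Pearson correlation
#'
#' @inheritParams pearsonR
#' @return R-squared in [0, 1].
#' @export
rSquared <- function(x, y) pearsonR(x, y)^2

#' Lag of the cross-correlation peak
#'
#' Finds the lag maximizing the normalized cross-correlation between two
#' series, with parabolic sub-frame refinement around the discrete peak.
#' Positive lag means \code{y} follows \code{x} (y is a delayed copy of x).
#'
#' @param x,y equal-length non-constant series.
#' @param frameRateHz sampling rate (Hz).
#' @param maxLagS maximum |lag| searched, in seconds.
#' @return lag in seconds.
#' @export
xcorrPeakLag <- function(x, y, frameRateHz, maxLagS) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  L <- round(maxLagS * frameRateHz)
  if (L >= n - 2) stop("maxLagS too large for series length")
  lags <- (-L):L
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x[1:(n - k)], y[(1 + k):n])
    else stats::cor(x[(1 - k):n], y[1:(n + k)])
  }, numeric(1))
  if (all(!is.finite(cc)) || max(cc) - min(cc) < 1e-12)
    stop("flat cross-correlation: no peak")
  i <- which.max(cc)
  delta <- 0
  if (i > 1 && i < length(cc)) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(denom) > 1e-12) delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
    delta <- max(min(delta, 0.5), -0.5)
  }
  (lags[i] + delta) / frameRateHz
}

#' Voxelwise condition-difference map
#'
#' Per voxel, the mean over frames of condition A minus the mean over frames
#' of condition B. Swapping the conditions negates the map exactly. By
#' convention the positive side is displayed green and the negative magenta
#' (configurable).
#'
#' @param vs a dF/F \linkS4class{VolumeSeries}.
#' @param framesA,framesB nonempty, disjoint frame index sets.
#' @param conditionA,conditionB condition names.
#' @param colorConvention named character: display colors for positive and
#'   negative values.
#' @return A \linkS4class{ConditionMap}.
#' @export
conditionDifferenceMap <- function(vs, framesA, framesB,
                                   conditionA = "A", conditionB = "B",
                                   colorConvention = c(positive = "green",
                                                       negative = "magenta")) {
  stopifnot(is(vs, "VolumeSeries"))
  if (!length(framesA) || !length(framesB)) stop("empty frame set")
  if (length(intersect(framesA, framesB)))
    stop("frame sets must be disjoint")
  X <- flattenVolumes(vs@data)
  vals <- rowMeans(X[, framesA, drop = FALSE]) -
    rowMeans(X[, framesB, drop = FALSE])
  new("ConditionMap", values = array(vals, dim(vs@data)[1:3]),
      conditionA = conditionA, conditionB = conditionB,
      colorConvention = colorConvention)
}

#' Stimulus-response map
#'
#' Per voxel, the mean over all 1-s (configurable) post-onset windows minus
#' the mean over all pre-onset windows. Onsets without a full window of data
#' on both sides are dropped and reported.
#'
#' @param vs a dF/F \linkS4class{VolumeSeries}.
#' @param onsetsS stimulus onset times in seconds.
#' @param windowS window length (s) on each side of the onset.
#' @return A \linkS4class{ConditionMap} (condition A = post, B = pre).
#' @export
stimulusResponseMap <- function(vs, onsetsS, windowS = 1) {
  stopifnot(is(vs, "VolumeSeries"))
  rate <- vs@frameRate
  nt <- nFrames(vs)
  w <- round(windowS * rate)
  if (w < 1) stop("window too short at this frame rate")
  onsetFrame <- round(onsetsS * rate) + 1L
  ok <- onsetFrame - w >= 1L & onsetFrame + w <= nt
  if (any(!ok))
    message(sum(!ok), " onset(s) dropped: too close to the recording edge")
  onsetFrame <- onsetFrame[ok]
  if (!length(onsetFrame)) stop("no onset has a full window on both sides")
  post <- unlist(lapply(onsetFrame, function(f) (f + 1L):(f + w)))
  pre <- unlist(lapply(onsetFrame, function(f) (f - w + 1L):f))
  X <- flattenVolumes(vs@data)
  vals <- rowMeans(X[, post, drop = FALSE]) - rowMeans(X[, pre, drop = FALSE])
  new("ConditionMap", values = array(vals, dim(vs@data)[1:3]),
      conditionA = "post", conditionB = "pre")
}

#' Permutation sign test for a condition-difference map
#'
#' One-sided voxelwise p-values for the observed A-minus-B mean difference
#' being positive, under circular shifts of the frame labels (preserving the
#' temporal autocorrelation of the conditions).
#'
#' @param vs a \linkS4class{VolumeSeries}.
#' @param framesA,framesB frame index sets.
#' @param nPerm number of circular shifts.
#' @param seed integer seed.
#' @param minShiftS minimum |shift| in seconds; shifts shorter than the
#'   indicator impulse response leave the labels aligned with the lagged
#'   fluorescence and do not form a valid null, so they are excluded
#'   (standard circular-shift practice).
#' @return 3D array of p-values.
#' @export
mapPermutationTest <- function(vs, framesA, framesB, nPerm = 199, seed = 1,
                               minShiftS = 5) {
  X <- flattenVolumes(vs@data)
  nt <- ncol(X)
  a <- numeric(nt); a[framesA] <- 1 / length(framesA)
  b <- numeric(nt); b[framesB] <- 1 / length(framesB)
  w <- a - b
  obs <- as.numeric(X %*% w)
  exceed <- numeric(length(obs))
  margin <- min(round(minShiftS * vs@frameRate), floor((nt - 1) / 3))
  pool <- setdiff(seq_len(nt - 1L),
                  c(seq_len(margin), nt - seq_len(margin)))
  if (!length(pool)) stop("recording too short for the shift margin")
  withSeed(seed, {
    shifts <- if (length(pool) <= nPerm) pool else sample(pool, nPerm)
    for (s in shifts) {
      wp <- c(w[(s + 1L):nt], w[1:s])
      exceed <- exceed + (as.numeric(X %*% wp) >= obs)
    }
    p <- (1 + exceed) / (1 + length(shifts))
  })
  array(p, dim(vs@data)[1:3])
}

#' Normalized per-region counts of responsive components
#'
#' Counts, per atlas region, the non-artifact components whose time series
#' correlate with a regressor above \code{rMin}, normalized by the count of
#' the most responsive region.
#'
#' @param cs a region-sorted \linkS4class{ComponentSet}.
#' @param regressor numeric regressor on the component-trace timescale.
#' @param rMin correlation threshold.
#' @param atlas optional \linkS4class{RegionAtlas} defining the region
#'   universe (otherwise the labels present in \code{cs} are used).
#' @return named numeric vector of normalized counts in [0, 1].
#' @export
countResponsive <- function(cs, regressor, rMin = 0.1, atlas = NULL) {
  stopifnot(is(cs, "ComponentSet"))
  if (all(cs@regionLabel == "unassigned"))
    stop("components must be region-sorted first (see sortByRegion)")
  regions <- if (!is.null(atlas)) unname(atlas@regionNames)
  else setdiff(unique(cs@regionLabel), "unassigned")
  counts <- stats::setNames(numeric(length(regions)), regions)
  for (i in seq_len(nComponents(cs))) {
    if (cs@artifact[i] != "activity") next
    lab <- cs@regionLabel[i]
    if (!lab %in% regions) next
    tr <- cs@traces[, i]
    if (stats::sd(tr) == 0) next
    if (stats::cor(tr, regressor) > rMin) counts[lab] <- counts[lab] + 1
  }
  if (max(counts) == 0) {
    warning("no responsive components in any region")
    return(counts)
  }
  counts / max(counts)
}

#' Render a two-color (green/magenta) map over a background
#'
#' Per z-slice 8-bit-style RGB rendering: the positive side of the map is
#' painted in one channel set and the negative side in the complementary one,
#' per the map's recorded color convention, on top of a grayscale background.
#' Overlay intensity is scaled to the map's absolute maximum.
#'
#' @param map a \linkS4class{ConditionMap}.
#' @param background 3D field on the same grid.
#' @param path optional directory; per-slice PNGs are written there.
#' @return invisibly, a list of (x, y, 3) RGB arrays in [0, 1], one per slice.
#' @export
exportTwocolor <- function(map, background, path = NULL) {
  stopifnot(is(map, "ConditionMap"))
  v <- map@values
  if (!all(dim(background) == dim(v)))
    stop("map and background must share a grid")
  mx <- max(abs(v))
  if (mx == 0) {
    warning("all-zero map: background-only image")
    ov <- array(0, dim(v))
  } else ov <- v / mx
  bg <- background - min(background)
  if (max(bg) > 0) bg <- bg / max(bg)
  greenPos <- identical(unname(map@colorConvention["positive"]), "green")
  slices <- lapply(seq_len(dim(v)[3]), function(z) {
    b <- 0.5 * bg[, , z]
    pos <- 0.5 * pmax(ov[, , z], 0)
    neg <- 0.5 * pmax(-ov[, , z], 0)
    g <- if (greenPos) pos else neg
    m <- if (greenPos) neg else pos    # magenta = red + blue
    rgb <- array(0, c(dim(b), 3L))
    rgb[, , 1] <- pmin(b + m, 1)
    rgb[, , 2] <- pmin(b + g, 1)
    rgb[, , 3] <- pmin(b + m, 1)
    rgb
  })
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_along(slices))
      png::writePNG(aperm(slices[[z]], c(2, 1, 3)),
                    file.path(path, sprintf("slice_%03d.png", z)))
  }
  invisible(slices)
}
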