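#' @import methods
NULL

#' VolumeSeries: a 4D fluorescence movie
#'
#' The pipeline's universal currency: a 4D scalar field (x, y, z, t) with the
#' physical voxel size, the acquisition frame rate, the indicator expressed in
#' the preparation, and an append-only provenance trail naming every operation
#' that has touched the data.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, t); x is the fastest axis.
#' @slot voxelSize numeric length 3, voxel pitch in micrometers (dx, dy, dz).
#' @slot frameRate acquisition rate in Hz.
#' @slot probe one of \code{"gcamp6f"}, \code{"gcamp6s"}, \code{"arclight"},
#'   \code{"gfp"}.
#' @slot provenance character vector of applied operations, append-only.
#' @export
setClass("VolumeSeries",
  representation(
    data = "array",
    voxelSize = "numeric",
    frameRate = "numeric",
    probe = "character",
    provenance = "character"
  ),
  prototype(
    voxelSize = c(3, 3, 6),
    frameRate = 100,
    probe = "gcamp6f",
    provenance = character(0)
  )
)

.validVolumeSeries <- function(object) {
  msgs <- character(0)
  if (length(dim(object@data)) != 4L)
    msgs <- c(msgs, "data must be a 4D array (x, y, z, t)")
  if (!all(is.finite(object@data)))
    msgs <- c(msgs, "data must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive values (um)")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msgs <- c(msgs, "frameRate must be a single positive number (Hz)")
  if (!object@probe %in% c("gcamp6f", "gcamp6s", "arclight", "gfp"))
    msgs <- c(msgs, "probe must be gcamp6f, gcamp6s, arclight or gfp")
  if (length(msgs)) msgs else TRUE
}
setValidity("VolumeSeries", .validVolumeSeries)

#' RegionAtlas: labeled 3D brain volume with landmarks
#'
#' Integer labels (0 = background), a label-to-name map, and named landmark
#' points in physical coordinates used for affine registration.
#'
#' @slot labels 3D integer array; 0 is background, 1..n are regions.
#' @slot regionNames named character vector mapping label (as name) to region
#'   name.
#' @slot landmarks numeric matrix n x 3 with unique rownames; physical
#'   coordinates in micrometers.
#' @slot voxelSize numeric length 3 (um).
#' @export
setClass("RegionAtlas",
  representation(
    labels = "array",
    regionNames = "character",
    landmarks = "matrix",
    voxelSize = "numeric"
  )
)

setValidity("RegionAtlas", function(object) {
  msgs <- character(0)
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs != 0L]
  if (!all(as.character(labs) %in% names(object@regionNames)))
    msgs <- c(msgs, "every nonzero label must have a region name")
  if (anyDuplicated(rownames(object@landmarks)))
    msgs <- c(msgs, "landmark names must be unique")
  if (ncol(object@landmarks) != 3L)
    msgs <- c(msgs, "landmarks must be an n x 3 matrix")
  if (length(msgs)) msgs else TRUE
})

#' BehaviorTrace: per-frame behavior state and ball optic flow
#'
#' @slot frameRate behavior sampling rate in Hz.
#' @slot state factor with levels rest, walk, groom; one entry per frame.
#' @slot flowLeft,flowRight nonnegative per-frame ball angular speed (a.u.);
#'   a turn is one-sided, so elementwise flowLeft * flowRight == 0.
#' @export
setClass("BehaviorTrace",
  representation(
    frameRate = "numeric",
    state = "factor",
    flowLeft = "numeric",
    flowRight = "numeric"
  )
)

setValidity("BehaviorTrace", function(object) {
  msgs <- character(0)
  if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
  if (!all(levels(object@state) %in% c("rest", "walk", "groom")))
    msgs <- c(msgs, "state levels must be within {rest, walk, groom}")
  n <- length(object@state)
  if (length(object@flowLeft) != n || length(object@flowRight) != n)
    msgs <- c(msgs, "state and flow traces must have equal length")
  if (any(object@flowLeft < 0) || any(object@flowRight < 0))
    msgs <- c(msgs, "flow must be nonnegative")
  if (any(object@flowLeft * object@flowRight != 0))
    msgs <- c(msgs, "a turn is one-sided: flowLeft * flowRight must be 0 per frame")
  if (length(msgs)) msgs else TRUE
})

#' StimulusTrain: stimulus onset/offset events
#'
#' @slot events data.frame with columns onset_s, offset_s, modality
#'   (\code{"light"} or \code{"odor"}); events within one modality do not
#'   overlap.
#' @export
setClass("StimulusTrain", representation(events = "data.frame"))

setValidity("StimulusTrain", function(object) {
  ev <- object@events
  msgs <- character(0)
  need <- c("onset_s", "offset_s", "modality")
  if (!all(need %in% names(ev)))
    return("events must have columns onset_s, offset_s, modality")
  if (nrow(ev)) {
    if (any(ev$onset_s >= ev$offset_s))
      msgs <- c(msgs, "onset_s must precede offset_s")
    if (!all(ev$modality %in% c("light", "odor")))
      msgs <- c(msgs, "modality must be light or odor")
    for (m in unique(ev$modality)) {
      sub <- ev[ev$modality == m, , drop = FALSE]
      sub <- sub[order(sub$onset_s), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$onset_s[-1] < sub$offset_s[-nrow(sub)]))
        msgs <- c(msgs, sprintf("events overlap within modality '%s'", m))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GroundTruth: a seeded phantom for the whole pipeline
#'
#' Per-source nonnegative spatial weight fields and fluorescence time series,
#' a rigid motion path, a multiplicative photobleaching curve, and the behavior
#' and stimulus trains the sources may be coupled to. Rendering a movie from a
#' GroundTruth is a deterministic function of its fields and a seed.
#'
#' @slot sourceMaps 4D array (x, y, z, source) of nonnegative weights.
#' @slot sourceTraces matrix (frame x source) of fluorescence (a.u.).
#' @slot sourceRegion integer atlas label hosting each source.
#' @slot motionPath matrix (frame x 3), rigid shift in voxels; row 1 is 0.
#' @slot bleachCurve per-frame multiplicative factor in (0, 1], non-increasing.
#' @slot behavior a \linkS4class{BehaviorTrace}.
#' @slot stimuli a \linkS4class{StimulusTrain}.
#' @slot frameRate imaging frame rate (Hz).
#' @slot probe indicator name.
#' @slot coupling character per source: what drives its trace.
#' @slot seed integer seed the phantom was generated with.
#' @export
setClass("GroundTruth",
  representation(
    sourceMaps = "array",
    sourceTraces = "matrix",
    sourceRegion = "integer",
    motionPath = "matrix",
    bleachCurve = "numeric",
    behavior = "BehaviorTrace",
    stimuli = "StimulusTrain",
    frameRate = "numeric",
    probe = "character",
    coupling = "character",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character(0)
  if (any(object@sourceMaps < 0) || !all(is.finite(object@sourceMaps)))
    msgs <- c(msgs, "source maps must be nonnegative and finite")
  if (any(diff(object@bleachCurve) > 1e-12))
    msgs <- c(msgs, "bleachCurve must be non-increasing")
  if (any(object@bleachCurve <= 0) || any(object@bleachCurve > 1))
    msgs <- c(msgs, "bleachCurve must lie in (0, 1]")
  if (nrow(object@motionPath) && any(object@motionPath[1, ] != 0))
    msgs <- c(msgs, "motionPath must start at (0,0,0)")
  if (ncol(object@sourceMaps) != 0 &&
      dim(object@sourceMaps)[4] != ncol(object@sourceTraces))
    msgs <- c(msgs, "one trace per source map required")
  if (length(msgs)) msgs else TRUE
})

#' RigidMotion: per-frame rigid motion estimate
#'
#' @slot translation matrix (frame x 3), voxels.
#' @slot rotation matrix (frame x 3), degrees; all-zero when rotation is not
#'   estimated.
#' @export
setClass("RigidMotion",
  representation(translation = "matrix", rotation = "matrix")
)

setValidity("RigidMotion", function(object) {
  msgs <- character(0)
  if (ncol(object@translation) != 3L) msgs <- c(msgs, "translation must be n x 3")
  if (!all(is.finite(object@translation))) msgs <- c(msgs, "translation must be finite")
  if (nrow(object@rotation) && nrow(object@rotation) != nrow(object@translation))
    msgs <- c(msgs, "rotation and translation must cover the same frames")
  if (length(msgs)) msgs else TRUE
})

#' PSFLibrary: depth-indexed lateral blur kernels
#'
#' Geometric-optics stand-in for a light field point spread function library:
#' one normalized lateral Gaussian kernel per reconstruction depth, widening
#' with distance from the focal plane.
#'
#' @slot depths signed focal offsets in micrometers, strictly increasing.
#' @slot kernels list of 2D nonnegative kernels, each summing to 1.
#' @slot sigmaLat lateral Gaussian sigma per depth (um).
#' @slot voxelSize numeric length 3 (um).
#' @export
setClass("PSFLibrary",
  representation(
    depths = "numeric",
    kernels = "list",
    sigmaLat = "numeric",
    voxelSize = "numeric"
  )
)

setValidity("PSFLibrary", function(object) {
  msgs <- character(0)
  if (is.unsorted(object@depths, strictly = TRUE))
    msgs <- c(msgs, "depths must be strictly increasing")
  sums <- vapply(object@kernels, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-9))
    msgs <- c(msgs, "each kernel must sum to 1 within 1e-9")
  if (any(vapply(object@kernels, function(k) any(k < 0), logical(1))))
    msgs <- c(msgs, "kernels must be nonnegative")
  if (length(object@kernels) != length(object@depths))
    msgs <- c(msgs, "one kernel per depth required")
  if (length(msgs)) msgs else TRUE
})

#' LightFieldSeries: raw 2D sensor frames over time
#'
#' @slot frames 3D array (px, py, t) of nonnegative sensor values.
#' @slot lensletPitch microlens pitch in sensor pixels; frame dims must be
#'   divisible by it.
#' @slot frameRate acquisition rate (Hz).
#' @export
setClass("LightFieldSeries",
  representation(
    frames = "array",
    lensletPitch = "integer",
    frameRate = "numeric"
  )
)

setValidity("LightFieldSeries", function(object) {
  msgs <- character(0)
  d <- dim(object@frames)
  if (length(d) != 3L) msgs <- c(msgs, "frames must be a 3D array (px, py, t)")
  else if (any(d[1:2] %% object@lensletPitch != 0))
    msgs <- c(msgs, "frame dims must be divisible by lensletPitch")
  if (any(object@frames < 0)) msgs <- c(msgs, "pixel values must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' SingularSpectrum: thin SVD of a voxels-by-time matrix
#'
#' @slot values all singular values, non-increasing.
#' @slot spatialModes voxels x k matrix of orthonormal spatial modes (top k).
#' @slot temporalModes frames x k matrix of orthonormal temporal modes.
#' @slot spatialDim the (x, y, z) grid the spatial modes fold back into.
#' @export
setClass("SingularSpectrum",
  representation(
    values = "numeric",
    spatialModes = "matrix",
    temporalModes = "matrix",
    spatialDim = "integer"
  )
)

setValidity("SingularSpectrum", function(object) {
  msgs <- character(0)
  if (any(diff(object@values) > 1e-8 * max(object@values, 1)))
    msgs <- c(msgs, "singular values must be non-increasing")
  if (ncol(object@spatialModes) != ncol(object@temporalModes))
    msgs <- c(msgs, "spatial and temporal mode counts must match")
  if (length(msgs)) msgs else TRUE
})

#' ComponentSet: paired spatial maps and time series from PCA/ICA
#'
#' @slot maps 4D array (x, y, z, component) of spatial weights (z-scorable).
#' @slot traces matrix (frame x component), variance normalized.
#' @slot traceScale per-component scale such that maps x (traceScale * traces)
#'   reconstructs the truncated data the components were unmixed from.
#' @slot signFixed logical: has the map-sign convention been applied.
#' @slot regionLabel per-component region name or \code{"unassigned"}.
#' @slot artifact per-component flag: activity, movement, aliasing, noise or
#'   manual.
#' @slot nRegionsPresent,nObjects per-component annotation counts (NA until
#'   computed).
#' @slot meta free-form list (convergence info, parameters).
#' @export
setClass("ComponentSet",
  representation(
    maps = "array",
    traces = "matrix",
    traceScale = "numeric",
    signFixed = "logical",
    regionLabel = "character",
    artifact = "character",
    nRegionsPresent = "integer",
    nObjects = "integer",
    meta = "list"
  )
)

setValidity("ComponentSet", function(object) {
  msgs <- character(0)
  k <- dim(object@maps)[4]
  if (ncol(object@traces) != k)
    msgs <- c(msgs, "number of maps and traces must match")
  if (length(object@regionLabel) != k || length(object@artifact) != k)
    msgs <- c(msgs, "per-component annotations must have one entry per component")
  ok <- c("activity", "movement", "aliasing", "noise", "manual")
  if (!all(object@artifact %in% ok))
    msgs <- c(msgs, "artifact flags must be within {activity, movement, aliasing, noise, manual}")
  if (length(msgs)) msgs else TRUE
})

#' RoiMask: thresholded nonnegative ROI weights for one component
#'
#' @slot weights 3D nonnegative field, zero outside the ROI.
#' @slot component index of the source component.
#' @slot thresholdK the k in the k-sigma threshold used to build the mask.
#' @export
setClass("RoiMask",
  representation(weights = "array", component = "integer", thresholdK = "numeric")
)

setValidity("RoiMask", function(object) {
  msgs <- character(0)
  if (any(object@weights < 0)) msgs <- c(msgs, "weights must be nonnegative")
  if (sum(object@weights) <= 0) msgs <- c(msgs, "mask must be nonempty")
  if (length(msgs)) msgs else TRUE
})

#' AffineTransform: 3x4 affine map in physical coordinates
#'
#' @slot matrix 3x4 matrix (linear part | translation), micrometers.
#' @slot residualRms RMS landmark residual of the fit (um), if known.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", residualRms = "numeric")
)

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(3, 4))) return("matrix must be 3 x 4")
  if (abs(det(m[, 1:3])) <= 1e-9) return("linear part must be invertible")
  TRUE
})

#' ConditionMap: voxelwise mean activity difference between two conditions
#'
#' @slot values signed 3D field (mean dF/F difference, dimensionless).
#' @slot conditionA,conditionB condition names; positive values mean A > B.
#' @slot colorConvention named character of length 2: display colors for the
#'   positive and negative sides.
#' @export
setClass("ConditionMap",
  representation(
    values = "array",
    conditionA = "character",
    conditionB = "character",
    colorConvention = "character"
  ),
  prototype(colorConvention = c(positive = "green", negative = "magenta"))
)

setValidity("ConditionMap", function(object) {
  msgs <- character(0)
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, "values must be a 3D array")
  if (!all(is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (!all(c("positive", "negative") %in% names(object@colorConvention)))
    msgs <- c(msgs, "colorConvention must name 'positive' and 'negative'")
  if (length(msgs)) msgs else TRUE
})

#' Kernel: discrete indicator impulse response
#'
#' Peak-normalized double-exponential impulse response of a fluorescent
#' activity indicator, sampled at the imaging frame rate.
#'
#' @slot taps nonnegative impulse response, max tap = 1.
#' @slot riseToPeak time from impulse to peak (s).
#' @slot frameRate sampling rate (Hz).
#' @slot probe indicator name.
#' @export
setClass("Kernel",
  representation(
    taps = "numeric",
    riseToPeak = "numeric",
    frameRate = "numeric",
    probe = "character"
  )
)

setValidity("Kernel", function(object) {
  msgs <- character(0)
  if (any(object@taps < 0)) msgs <- c(msgs, "taps must be nonnegative")
  if (abs(max(object@taps) - 1) > 1e-9)
    msgs <- c(msgs, "kernel must be peak-normalized (max tap = 1)")
  dt <- 1 / object@frameRate
  if (abs((which.max(object@taps) - 1) * dt - object@riseToPeak) > dt + 1e-9)
    msgs <- c(msgs, "argmax of taps must sit at riseToPeak within one sample")
  if (length(msgs)) msgs else TRUE
})
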