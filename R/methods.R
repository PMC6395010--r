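#' @include AllClasses.R
NULL

# ---- constructors -----------------------------------------------------------

#' Create a VolumeSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelSize voxel pitch in micrometers, length 3.
#' @param frameRate frame rate in Hz.
#' @param probe indicator: gcamp6f, gcamp6s, arclight or gfp.
#' @param provenance character vector of operations already applied.
#' @return A \linkS4class{VolumeSeries}.
#' @examples
#' vs <- VolumeSeries(array(1, c(4, 4, 2, 10)), frameRate = 50)
#' dim(vs)
#' @export
VolumeSeries <- function(data, voxelSize = c(3, 3, 6), frameRate = 100,
                         probe = "gcamp6f", provenance = character(0)) {
  new("VolumeSeries", data = data, voxelSize = as.numeric(voxelSize),
      frameRate = frameRate, probe = probe, provenance = provenance)
}

# ---- accessors --------------------------------------------------------------

#' Accessors for pipeline objects
#'
#' \code{volData} returns the raw 4D array of a VolumeSeries; \code{voxelSize},
#' \code{frameRate}, \code{probe} and \code{provenance} return the
#' corresponding metadata. \code{nFrames} counts time points.
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setMethod("volData", "VolumeSeries", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeSeries", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "RegionAtlas", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "VolumeSeries", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "BehaviorTrace", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("probe", function(object) standardGeneric("probe"))
#' @rdname accessors
#' @export
setMethod("probe", "VolumeSeries", function(object) object@probe)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "VolumeSeries", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "VolumeSeries", function(object) dim(object@data)[4])
#' @rdname accessors
#' @export
setMethod("nFrames", "BehaviorTrace", function(object) length(object@state))

#' @rdname accessors
#' @export
setMethod("dim", "VolumeSeries", function(x) dim(x@data))

#' @rdname accessors
#' @export
setGeneric("componentMaps", function(object) standardGeneric("componentMaps"))
#' @rdname accessors
#' @export
setMethod("componentMaps", "ComponentSet", function(object) object@maps)

#' @rdname accessors
#' @export
setGeneric("componentTraces", function(object) standardGeneric("componentTraces"))
#' @rdname accessors
#' @export
setMethod("componentTraces", "ComponentSet", function(object) object@traces)

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "ComponentSet", function(object) dim(object@maps)[4])

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "ComponentSet", function(object) object@regionLabel)
#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionAtlas", function(object) object@regionNames)

#' @rdname accessors
#' @export
setGeneric("artifactFlags", function(object) standardGeneric("artifactFlags"))
#' @rdname accessors
#' @export
setMethod("artifactFlags", "ComponentSet", function(object) object@artifact)

#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(object) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setMethod("atlasLabels", "RegionAtlas", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("landmarks", function(object) standardGeneric("landmarks"))
#' @rdname accessors
#' @export
setMethod("landmarks", "RegionAtlas", function(object) object@landmarks)

#' @rdname accessors
#' @export
setGeneric("behaviorState", function(object) standardGeneric("behaviorState"))
#' @rdname accessors
#' @export
setMethod("behaviorState", "BehaviorTrace", function(object) object@state)

#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setMethod("singularValues", "SingularSpectrum", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("kernelTaps", function(object) standardGeneric("kernelTaps"))
#' @rdname accessors
#' @export
setMethod("kernelTaps", "Kernel", function(object) object@taps)

#' @rdname accessors
#' @export
setGeneric("stimulusEvents", function(object) standardGeneric("stimulusEvents"))
#' @rdname accessors
#' @export
setMethod("stimulusEvents", "StimulusTrain", function(object) object@events)

# append a provenance record; internal
.stamp <- function(vs, what) {
  vs@provenance <- c(vs@provenance, what)
  vs
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d voxels, %d frames @ %g Hz\n",
              d[1], d[2], d[3], d[4], object@frameRate))
  cat(sprintf("  voxel size (um): %g x %g x %g | probe: %s\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@probe))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "RegionAtlas", function(object) {
  d <- dim(object@labels)
  cat(sprintf("RegionAtlas: %d x %d x %d voxels, %d regions, %d landmarks\n",
              d[1], d[2], d[3], length(object@regionNames),
              nrow(object@landmarks)))
})

setMethod("show", "BehaviorTrace", function(object) {
  tab <- table(object@state)
  cat(sprintf("BehaviorTrace: %d frames @ %g Hz (%s)\n",
              length(object@state), object@frameRate,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "StimulusTrain", function(object) {
  cat(sprintf("StimulusTrain: %d events (%s)\n", nrow(object@events),
              paste(unique(object@events$modality), collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  d <- dim(object@sourceMaps)
  cat(sprintf("GroundTruth: %d sources on %d x %d x %d grid, %d frames @ %g Hz, probe %s\n",
              d[4], d[1], d[2], d[3], nrow(object@sourceTraces),
              object@frameRate, object@probe))
})

setMethod("show", "PSFLibrary", function(object) {
  cat(sprintf("PSFLibrary: %d depths from %g to %g um, lateral sigma %g-%g um\n",
              length(object@depths), min(object@depths), max(object@depths),
              min(object@sigmaLat), max(object@sigmaLat)))
})

setMethod("show", "LightFieldSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("LightFieldSeries: %d x %d sensor, %d frames @ %g Hz, lenslet pitch %d px\n",
              d[1], d[2], d[3], object@frameRate, object@lensletPitch))
})

setMethod("show", "SingularSpectrum", function(object) {
  cat(sprintf("SingularSpectrum: %d singular values (%.3g .. %.3g), %d modes retained\n",
              length(object@values), object@values[1],
              object@values[length(object@values)], ncol(object@spatialModes)))
})

setMethod("show", "ComponentSet", function(object) {
  k <- dim(object@maps)[4]
  nart <- sum(object@artifact != "activity")
  cat(sprintf("ComponentSet: %d components (%d flagged as artifact), sign %s\n",
              k, nart, if (isTRUE(object@signFixed)) "fixed" else "free"))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (3x4, um):\n")
  print(round(object@matrix, 4))
  if (length(object@residualRms))
    cat(sprintf("  landmark residual RMS: %.4g um\n", object@residualRms))
})

setMethod("show", "ConditionMap", function(object) {
  cat(sprintf("ConditionMap: %s - %s, range [%.3g, %.3g] (%s positive / %s negative)\n",
              object@conditionA, object@conditionB, min(object@values),
              max(object@values), object@colorConvention["positive"],
              object@colorConvention["negative"]))
})

setMethod("show", "Kernel", function(object) {
  cat(sprintf("Kernel (%s): %d taps @ %g Hz, rise to peak %.3g s\n",
              object@probe, length(object@taps), object@frameRate,
              object@riseToPeak))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask: component %d, %d voxels, k = %g\n",
              object@component, sum(object@weights > 0), object@thresholdK))
})
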