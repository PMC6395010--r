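# NIfTI-1, TIFF, CSV and JSON readers/writers for the pipeline's objects.
# Volumes travel as 4D NIfTI with voxel size and frame period in the header
# and a JSON sidecar carrying probe and provenance; behavior and stimuli are
# plain CSV; atlases are integer-label NIfTI plus a JSON of names/landmarks.

.sidecarPath <- function(path) paste0(path, ".json")

#' Read and write 4D movies as NIfTI-1
#'
#' \code{writeVolume} stores the data as 4D NIfTI with the voxel size (um)
#' and frame period in pixdim, plus a JSON sidecar (\code{<path>.json}) with
#' probe and provenance. \code{readVolume} restores all of it;
#' write-then-read is the identity on the data and on every header field the
#' package uses.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param vs a \linkS4class{VolumeSeries}.
#' @return \code{readVolume}: a \linkS4class{VolumeSeries};
#'   \code{writeVolume}: the path, invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D NIfTI at ", path, " (got ", length(d), "D)")
  pd <- RNifti::pixdim(img)
  probe <- "gfp"; prov <- character(0); rate <- NULL
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    probe <- meta$probe %||% probe
    prov <- meta$provenance %||% prov
    rate <- meta$frame_rate_hz
  }
  if (is.null(rate)) rate <- if (length(pd) >= 4 && pd[4] > 0) 1 / pd[4] else 1
  VolumeSeries(array(as.numeric(img), d), voxelSize = pd[1:3],
               frameRate = rate, probe = probe,
               provenance = as.character(prov))
}

#' @rdname readVolume
#' @export
writeVolume <- function(vs, path) {
  stopifnot(is(vs, "VolumeSeries"))
  img <- RNifti::asNifti(vs@data)
  RNifti::pixdim(img) <- c(vs@voxelSize, 1 / vs@frameRate)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(probe = vs@probe, frame_rate_hz = vs@frameRate,
         voxel_size_um = vs@voxelSize, provenance = vs@provenance),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import raw light field frames from a multi-page TIFF
#'
#' @param path multi-page TIFF of uniform page size.
#' @param frameRateHz acquisition rate (Hz).
#' @param lensletPitchPx microlens pitch in pixels.
#' @param asIs read integer sample values as stored (preserved exactly as
#'   floats) instead of rescaling to [0, 1].
#' @return A \linkS4class{LightFieldSeries}.
#' @export
importTiffStack <- function(path, frameRateHz, lensletPitchPx = 4L,
                            asIs = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = asIs),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (!length(pages)) stop("empty TIFF: ", path)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF pages: all pages must share one size")
  # TIFF pages arrive row-major (y, x); store as (x, y, t)
  fr <- array(0, c(dims[2, 1], dims[1, 1], length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- t(pages[[t]])
  new("LightFieldSeries", frames = fr,
      lensletPitch = as.integer(lensletPitchPx), frameRate = frameRateHz)
}

#' Read and write behavior traces as CSV
#'
#' Columns: \code{time_s}, \code{state}, \code{flow_left},
#' \code{flow_right}. The frame rate is recovered from the time column.
#'
#' @param behavior a \linkS4class{BehaviorTrace}.
#' @param path CSV path.
#' @return \code{readBehavior}: a \linkS4class{BehaviorTrace}.
#' @export
writeBehavior <- function(behavior, path) {
  stopifnot(is(behavior, "BehaviorTrace"))
  n <- nFrames(behavior)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / behavior@frameRate,
    state = as.character(behavior@state),
    flow_left = behavior@flowLeft,
    flow_right = behavior@flowRight
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehavior
#' @export
readBehavior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rate <- 1 / stats::median(diff(df$time_s))
  new("BehaviorTrace", frameRate = rate,
      state = factor(df$state, levels = c("rest", "walk", "groom")),
      flowLeft = df$flow_left, flowRight = df$flow_right)
}

#' Read and write stimulus trains as CSV
#'
#' Columns: \code{onset_s}, \code{offset_s}, \code{modality}.
#'
#' @param stimuli a \linkS4class{StimulusTrain}.
#' @param path CSV path.
#' @return \code{readStimuli}: a \linkS4class{StimulusTrain}.
#' @export
writeStimuli <- function(stimuli, path) {
  stopifnot(is(stimuli, "StimulusTrain"))
  utils::write.csv(stimuli@events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStimuli
#' @export
readStimuli <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("StimulusTrain", events = df)
}

#' Read and write a region atlas
#'
#' The labels travel as integer NIfTI (\code{<base>_labels.nii.gz}); region
#' names and named landmarks as JSON (\code{<base>_meta.json}).
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param base path prefix.
#' @return \code{readAtlas}: a \linkS4class{RegionAtlas}.
#' @export
writeAtlas <- function(atlas, base) {
  stopifnot(is(atlas, "RegionAtlas"))
  img <- RNifti::asNifti(atlas@labels + 0L)
  RNifti::pixdim(img) <- atlas@voxelSize
  RNifti::writeNifti(img, paste0(base, "_labels.nii.gz"), datatype = "int32")
  jsonlite::write_json(
    list(region_names = as.list(atlas@regionNames),
         landmarks = apply(atlas@landmarks, 1, function(p) as.numeric(p),
                           simplify = FALSE),
         voxel_size_um = atlas@voxelSize),
    paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(base) {
  img <- RNifti::readNifti(paste0(base, "_labels.nii.gz"))
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  lm <- do.call(rbind, meta$landmarks)
  new("RegionAtlas", labels = array(as.integer(img), dim(img)),
      regionNames = unlist(meta$region_names),
      landmarks = lm, voxelSize = as.numeric(meta$voxel_size_um))
}

#' Write a component set to a directory
#'
#' Maps as one 4D NIfTI (component along the 4th axis), traces as CSV
#' (frame x component), annotations and metadata as JSON.
#'
#' @param cs a \linkS4class{ComponentSet}.
#' @param dir output directory (created if needed).
#' @param voxelSize voxel pitch recorded in the maps header.
#' @return \code{readComponents}: a \linkS4class{ComponentSet}.
#' @export
writeComponents <- function(cs, dir, voxelSize = c(3, 3, 6)) {
  stopifnot(is(cs, "ComponentSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(cs@maps)
  RNifti::pixdim(img) <- c(voxelSize, 1)
  RNifti::writeNifti(img, file.path(dir, "maps.nii.gz"))
  tr <- as.data.frame(cs@traces)
  names(tr) <- sprintf("component_%03d", seq_len(ncol(cs@traces)))
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(trace_scale = cs@traceScale, sign_fixed = cs@signFixed,
         region_label = cs@regionLabel, artifact = cs@artifact,
         n_regions_present = cs@nRegionsPresent, n_objects = cs@nObjects,
         meta = cs@meta),
    file.path(dir, "components.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeComponents
#' @export
readComponents <- function(dir) {
  mapsImg <- RNifti::readNifti(file.path(dir, "maps.nii.gz"))
  maps <- array(as.numeric(mapsImg), dim(mapsImg))
  tr <- as.matrix(utils::read.csv(file.path(dir, "traces.csv")))
  dimnames(tr) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "components.json"),
                              simplifyVector = TRUE)
  new("ComponentSet", maps = maps, traces = tr,
      traceScale = as.numeric(meta$trace_scale),
      signFixed = isTRUE(meta$sign_fixed),
      regionLabel = as.character(meta$region_label),
      artifact = as.character(meta$artifact),
      nRegionsPresent = as.integer(meta$n_regions_present),
      nObjects = as.integer(meta$n_objects),
      meta = as.list(meta$meta))
}

#' Save a ground-truth bundle to a directory
#'
#' Source maps as 4D NIfTI, traces/motion/bleach as CSV, behavior and
#' stimuli as CSV, plus a manifest JSON tying the pieces together.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
saveGroundTruth <- function(truth, dir) {
  stopifnot(is(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(truth@sourceMaps)
  RNifti::writeNifti(img, file.path(dir, "source_maps.nii.gz"))
  utils::write.csv(as.data.frame(truth@sourceTraces),
                   file.path(dir, "source_traces.csv"), row.names = FALSE)
  utils::write.csv(data.frame(dx = truth@motionPath[, 1],
                              dy = truth@motionPath[, 2],
                              dz = truth@motionPath[, 3],
                              bleach = truth@bleachCurve),
                   file.path(dir, "motion_bleach.csv"), row.names = FALSE)
  writeBehavior(truth@behavior, file.path(dir, "behavior.csv"))
  writeStimuli(truth@stimuli, file.path(dir, "stimuli.csv"))
  jsonlite::write_json(
    list(frame_rate_hz = truth@frameRate, probe = truth@probe,
         seed = truth@seed, coupling = truth@coupling,
         source_region = truth@sourceRegion,
         files = c("source_maps.nii.gz", "source_traces.csv",
                   "motion_bleach.csv", "behavior.csv", "stimuli.csv")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
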