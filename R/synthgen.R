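# Seeded ground-truth phantom generation: atlas, behavior, stimuli, sources,
# and rendering into noisy, bleaching, moving 4D movies. Every downstream
# stage of the pipeline is tested against these known answers.

.regionNamePool <- c(
  "AL_L", "AL_R", "MB_L", "MB_R", "EB", "FB", "PB", "LH_L", "LH_R",
  "OL_L", "OL_R", "SLP_L", "SLP_R", "PS_L", "PS_R", "AMMC_L", "AMMC_R",
  "GNG", "NO", "SAD"
)

#' Generate a synthetic labeled region atlas
#'
#' Builds a brain-shaped (ellipsoidal) mask on a voxel grid and partitions it
#' into \code{nRegions} connected regions by Voronoi tessellation around
#' k-means centers of the mask voxels. Landmarks are placed at every region
#' centroid plus the mask pole points, so at least four non-coplanar named
#' landmarks always exist.
#'
#' @param shape integer length 3, voxel grid dimensions (each >= 8).
#' @param nRegions number of regions (>= 2).
#' @param seed integer seed; the atlas is a deterministic function of the
#'   arguments.
#' @param voxelSize voxel pitch in micrometers.
#' @return A \linkS4class{RegionAtlas}.
#' @examples
#' atl <- makeAtlas(c(16, 16, 8), 2, seed = 1)
#' table(atlasLabels(atl))
#' @export
makeAtlas <- function(shape, nRegions, seed, voxelSize = c(3, 3, 6)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, nRegions >= 2)
  if (any(shape < 8L))
    stop("shape too small: every dimension must be >= 8 voxels")
  withSeed(seed, {
    ctr <- (shape + 1) / 2
    semi <- 0.45 * shape
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
    r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
      ((g$z - ctr[3]) / semi[3])^2
    inside <- r2 <= 1
    if (sum(inside) < 8 * nRegions)
      stop("shape too small to host ", nRegions, " connected regions")
    pts <- as.matrix(g[inside, ])
    km <- stats::kmeans(pts, centers = nRegions, nstart = 3, iter.max = 50)
    # Voronoi labeling around the k-means centers: cells are convex, hence
    # each region is a connected set on the grid.
    cc <- km$centers
    d2 <- matrix(0, nrow(pts), nRegions)
    for (k in seq_len(nRegions))
      d2[, k] <- (pts[, 1] - cc[k, 1])^2 + (pts[, 2] - cc[k, 2])^2 +
        (pts[, 3] - cc[k, 3])^2
    lab <- max.col(-d2)
    labels <- array(0L, shape)
    labels[as.matrix(pts)] <- lab
    nms <- if (nRegions <= length(.regionNamePool))
      .regionNamePool[seq_len(nRegions)]
    else c(.regionNamePool,
           sprintf("region_%02d", seq_len(nRegions - length(.regionNamePool))))
    names(nms) <- as.character(seq_len(nRegions))
    vox <- as.numeric(voxelSize)
    centroids <- t(vapply(seq_len(nRegions), function(k) {
      colMeans(pts[lab == k, , drop = FALSE])
    }, numeric(3)))
    lm <- (centroids - 1) * rep(vox, each = nRegions)
    rownames(lm) <- paste0("centroid_", nms)
    poleIdx <- c(which.min(pts[, 2]), which.max(pts[, 2]),
                 which.max(pts[, 3]), which.min(pts[, 3]))
    poles <- (pts[poleIdx, , drop = FALSE] - 1) * rep(vox, each = 4)
    rownames(poles) <- c("anterior_pole", "posterior_pole",
                         "dorsal_pole", "ventral_pole")
    new("RegionAtlas", labels = labels, regionNames = nms,
        landmarks = rbind(lm, poles), voxelSize = vox)
  })
}

#' Generate a semi-Markov behavior trace
#'
#' Rest/walk/groom bouts with gamma-distributed durations around configurable
#' means, plus one-sided ball optic flow during walking (alternating turn
#' segments with smoothed nonnegative magnitude).
#'
#' @param durationS recording length in seconds.
#' @param frameRateHz behavior sampling rate.
#' @param seed integer seed.
#' @param meanBoutS named numeric: mean bout durations in seconds for walk,
#'   rest and groom.
#' @return A \linkS4class{BehaviorTrace}.
#' @export
makeBehavior <- function(durationS, frameRateHz, seed,
                         meanBoutS = c(walk = 5, rest = 8, groom = 3)) {
  stopifnot(durationS > 0, frameRateHz > 0)
  nt <- round(durationS * frameRateHz)
  withSeed(seed, {
    trans <- list(rest = c(walk = 0.6, groom = 0.4),
                  walk = c(rest = 0.7, groom = 0.3),
                  groom = c(rest = 0.7, walk = 0.3))
    state <- character(0)
    cur <- "rest"
    while (length(state) < nt) {
      len <- max(0.3, stats::rgamma(1, shape = 2, scale = meanBoutS[cur] / 2))
      state <- c(state, rep(cur, max(1L, round(len * frameRateHz))))
      pr <- trans[[cur]]
      cur <- sample(names(pr), 1, prob = pr)
    }
    state <- factor(state[seq_len(nt)], levels = c("rest", "walk", "groom"))
    flowL <- numeric(nt)
    flowR <- numeric(nt)
    walk <- which(state == "walk")
    if (length(walk)) {
      # split walking into runs, then into alternating turn segments
      runs <- split(walk, cumsum(c(1, diff(walk) != 1)))
      for (run in runs) {
        i <- 1L
        dir <- sample(c("L", "R"), 1)
        while (i <= length(run)) {
          seg <- max(1L, round(stats::rgamma(1, 2, scale = 1) * frameRateHz))
          idx <- run[i:min(length(run), i + seg - 1L)]
          mag <- abs(stats::filter(stats::rnorm(length(idx) + 20, 1, 0.3),
                                   rep(1 / 5, 5), sides = 2))
          mag <- mag[11:(10 + length(idx))]
          mag[is.na(mag)] <- 1
          if (dir == "L") flowL[idx] <- mag else flowR[idx] <- mag
          dir <- if (dir == "L") "R" else "L"
          i <- i + seg
        }
      }
    }
    new("BehaviorTrace", frameRate = frameRateHz, state = state,
        flowLeft = flowL, flowRight = flowR)
  })
}

#' Generate a periodic stimulus train
#'
#' Interleaved light and odor pulses; onsets of the two modalities are offset
#' by half a period so events never coincide.
#'
#' @param durationS recording length (s).
#' @param periodS inter-onset period within one modality (s).
#' @param pulseS pulse duration (s).
#' @param modalities which modalities to include.
#' @param startS time of the first onset (s).
#' @return A \linkS4class{StimulusTrain}.
#' @export
makeStimuli <- function(durationS, periodS = 10, pulseS = 0.5,
                        modalities = c("light", "odor"), startS = 5) {
  ev <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                   modality = character(0))
  for (i in seq_along(modalities)) {
    first <- startS + (i - 1) * periodS / length(modalities)
    last <- durationS - pulseS - 1
    on <- if (first <= last) seq(first, last, by = periodS) else numeric(0)
    if (length(on))
      ev <- rbind(ev, data.frame(onset_s = on, offset_s = on + pulseS,
                                 modality = modalities[i]))
  }
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  new("StimulusTrain", events = ev)
}

# normalize the coupling argument into a list of specs
.normCoupling <- function(coupling, nSources) {
  if (is.null(coupling)) coupling <- rep("events", nSources)
  if (is.character(coupling)) coupling <- as.list(coupling)
  stopifnot(length(coupling) == nSources)
  lapply(coupling, function(cp) {
    if (is.character(cp)) cp <- list(type = cp)
    if (is.null(cp$gain)) cp$gain <- 1
    ok <- c("events", "walk", "groom", "flow_left", "flow_right",
            "stim_light", "stim_odor", "copy", "silent")
    if (!cp$type %in% ok) stop("unknown coupling type: ", cp$type)
    cp
  })
}

#' Generate ground-truth sources, traces, motion and bleaching
#'
#' Places \code{nSources} smooth compact blobs, each inside exactly one atlas
#' region, and builds their fluorescence traces by convolving a driver signal
#' (a random event train, a behavior-state indicator, ball optic flow, or a
#' stimulus onset train) with the indicator impulse-response kernel. A
#' photobleaching curve (exponential decay parameterized by the fractional
#' loss over 30 s) and a smooth rigid motion path are generated alongside.
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param nSources number of sources (at most 4 per region).
#' @param probe indicator: gcamp6f, gcamp6s or arclight.
#' @param durationS recording length (s); \code{durationS * frameRateHz} must
#'   be at least 64 frames and exceed the kernel length.
#' @param frameRateHz imaging frame rate (Hz).
#' @param seed integer seed.
#' @param coupling per-source driver: a character vector (\code{"events"},
#'   \code{"walk"}, \code{"groom"}, \code{"flow_left"}, \code{"flow_right"},
#'   \code{"stim_light"}, \code{"stim_odor"}, \code{"silent"}) or a list of
#'   specs; \code{list(type = "copy", of = j, delayS = d)} copies source j's
#'   trace delayed by d seconds. Default: independent event trains.
#' @param amplitude peak fluorescence of each source trace (a.u. over
#'   baseline).
#' @param eventRateHz Poisson rate of the event trains.
#' @param bleachLossPer30s fractional intensity loss over 30 s; defaults to
#'   0.13 for GCaMP6 and 0.20 for ArcLight.
#' @param blobSigmaVox lateral Gaussian radius of the source blobs (voxels).
#' @return A \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(atlas, nSources, probe = "gcamp6f", durationS,
                            frameRateHz, seed, coupling = NULL,
                            amplitude = 30, eventRateHz = 0.3,
                            bleachLossPer30s = NULL, blobSigmaVox = 1.8) {
  stopifnot(is(atlas, "RegionAtlas"))
  nRegions <- length(atlas@regionNames)
  if (nSources > nRegions * 4)
    stop("too many sources: at most 4 per atlas region")
  nt <- round(durationS * frameRateHz)
  if (nt < 64) stop("need at least 64 frames (durationS * frameRateHz)")
  kern <- makeKernel(probe, frameRateHz)
  if (nt < length(kern@taps))
    stop("frame count is shorter than the probe kernel")
  if (is.null(bleachLossPer30s))
    bleachLossPer30s <- if (probe == "arclight") 0.20 else 0.13
  coupling <- .normCoupling(coupling, nSources)
  shape <- dim(atlas@labels)
  behavior <- makeBehavior(durationS, frameRateHz, seed = seed + 1L)
  stimuli <- makeStimuli(durationS)
  withSeed(seed, {
    # one region per source, cycling when nSources > nRegions
    regionOrder <- rep(sample(nRegions), length.out = nSources)
    maps <- array(0, c(shape, nSources))
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
    for (s in seq_len(nSources)) {
      reg <- regionOrder[s]
      vox <- which(atlas@labels == reg, arr.ind = TRUE)
      ctr <- vox[sample(nrow(vox), 1), ]
      d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      blob <- exp(-d2 / (2 * blobSigmaVox^2))
      blob[as.integer(atlas@labels) != reg] <- 0   # support inside its region
      blob[blob < 0.05 * max(blob)] <- 0           # compact support
      maps[, , , s] <- blob / max(blob)
    }
    tSec <- (seq_len(nt) - 1) / frameRateHz
    ev <- stimuli@events
    onsetTrain <- function(modality) {
      tr <- numeric(nt)
      on <- ev$onset_s[ev$modality == modality]
      idx <- round(on * frameRateHz) + 1L
      tr[idx[idx >= 1 & idx <= nt]] <- 1
      tr
    }
    drivers <- list(
      walk = as.numeric(behavior@state == "walk"),
      groom = as.numeric(behavior@state == "groom"),
      flow_left = behavior@flowLeft,
      flow_right = behavior@flowRight,
      stim_light = onsetTrain("light"),
      stim_odor = onsetTrain("odor")
    )
    traces <- matrix(0, nt, nSources)
    for (s in seq_len(nSources)) {
      cp <- coupling[[s]]
      tr <- switch(cp$type,
        silent = numeric(nt),
        events = {
          # every event-driven source fires at least twice: a source with no
          # events is indistinguishable from background (use coupling
          # "silent" for that case)
          nEvents <- max(2L, stats::rpois(1, eventRateHz * durationS))
          tr0 <- numeric(nt)
          at <- sample(nt, min(nEvents, nt))
          tr0[at] <- stats::runif(length(at), 0.5, 1.5)
          tr0
        },
        copy = numeric(nt),   # filled after the pass
        drivers[[cp$type]]
      )
      if (cp$type != "copy") {
        conv <- convolveCausal(tr, kern@taps)
        if (max(abs(conv)) > 0)
          conv <- conv / max(abs(conv)) * amplitude * cp$gain
        traces[, s] <- conv
      }
    }
    for (s in seq_len(nSources)) {
      cp <- coupling[[s]]
      if (cp$type == "copy") {
        lagF <- round((cp$delayS %||% 0) * frameRateHz)
        src <- traces[, cp$of]
        traces[, s] <- c(numeric(lagF), src)[seq_len(nt)] * cp$gain
      }
    }
    lambda <- -log(1 - bleachLossPer30s) / 30
    bleach <- exp(-lambda * tSec)
    # smooth unit-amplitude rigid motion path; scaled at render time
    path <- apply(matrix(stats::rnorm(nt * 3), nt, 3), 2, cumsum)
    sm <- max(3L, round(frameRateHz))
    path <- apply(path, 2, function(p) {
      f <- stats::filter(p, rep(1 / sm, sm), sides = 2, circular = TRUE)
      as.numeric(f)
    })
    path <- sweep(path, 2, path[1, ])
    mx <- max(abs(path))
    if (mx > 0) path <- path / mx
    new("GroundTruth",
        sourceMaps = maps, sourceTraces = traces,
        sourceRegion = as.integer(regionOrder), motionPath = path,
        bleachCurve = bleach, behavior = behavior, stimuli = stimuli,
        frameRate = frameRateHz, probe = probe,
        coupling = vapply(coupling, `[[`, character(1), "type"),
        seed = as.integer(seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate an anatomical baseline fluorescence field
#'
#' Real recordings carry static anatomical contrast in the baseline (region
#' boundaries, tracts), which is what rigid registration locks onto. This
#' builds a positive 3D field with per-region intensity variation plus a
#' smooth within-region texture, dimmer outside the brain mask.
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param level mean baseline level inside the brain (a.u.).
#' @param contrast fractional per-region and textural intensity variation.
#' @param seed integer seed.
#' @return 3D positive array on the atlas grid.
#' @export
makeBaseline <- function(atlas, level = 100, contrast = 0.3, seed = 1) {
  stopifnot(is(atlas, "RegionAtlas"), level > 0)
  labs <- atlas@labels
  d <- dim(labs)
  withSeed(seed, {
    nReg <- length(atlas@regionNames)
    mult <- stats::runif(nReg, 1 - contrast, 1 + contrast)
    fld <- array(0.3, d)                       # dim background outside brain
    for (r in seq_len(nReg)) fld[labs == r] <- mult[r]
    tex <- array(stats::rnorm(prod(d)), d)
    for (a in 1:3) {                           # cheap separable smoothing
      tex <- (tex + shift3d(tex, replace(c(0, 0, 0), a, 1)) +
                shift3d(tex, replace(c(0, 0, 0), a, -1))) / 3
    }
    tex <- tex / max(abs(tex))
    pmax(level * (fld + 0.5 * contrast * tex), 0.05 * level)
  })
}

#' Render a ground-truth phantom into a noisy 4D movie
#'
#' Frame t is \code{shift(bleach[t] * (baseline + sum_s map_s * trace_s[t]),
#' motionAmpVoxels * motionPath[t]) + noise}. With zero motion and noise the
#' rendering is linear in the source traces. Deterministic given the seed.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param baseline baseline fluorescence: a positive scalar (flat baseline)
#'   or a positive 3D field on the source grid (anatomical baseline, see
#'   \code{\link{makeBaseline}}).
#' @param motionAmpVoxels peak rigid displacement in voxels (0 disables
#'   motion).
#' @param noise list with \code{gaussianSd} (read noise SD, a.u.) and
#'   \code{poissonScale} (0 disables shot noise; otherwise counts are drawn
#'   as Poisson with mean \code{value * poissonScale} and rescaled).
#' @param seed integer seed for the noise draw.
#' @param voxelSize voxel pitch (um) of the rendered movie.
#' @return A \linkS4class{VolumeSeries}.
#' @export
renderMovie <- function(truth, baseline = 100, motionAmpVoxels = 0,
                        noise = list(gaussianSd = 2, poissonScale = 0),
                        seed = 1, voxelSize = c(3, 3, 6)) {
  stopifnot(is(truth, "GroundTruth"))
  if (any(baseline <= 0)) stop("baseline must be > 0")
  gSd <- noise$gaussianSd %||% 0
  pSc <- noise$poissonScale %||% 0
  if (gSd < 0 || pSc < 0) stop("noise parameters must be nonnegative")
  shape <- dim(truth@sourceMaps)[1:3]
  if (!is.null(dim(baseline)) && !all(dim(baseline) == shape))
    stop("baseline field must match the source grid")
  nt <- nrow(truth@sourceTraces)
  M <- flattenVolumes(truth@sourceMaps)
  out <- M %*% t(truth@sourceTraces)       # voxels x frames
  out <- out + as.numeric(baseline)
  out <- sweep(out, 2, truth@bleachCurve, "*")
  if (motionAmpVoxels != 0) {
    for (t in seq_len(nt)) {
      sh <- motionAmpVoxels * truth@motionPath[t, ]
      if (any(sh != 0)) {
        fr <- array(out[, t], shape)
        out[, t] <- shift3d(fr, sh)
      }
    }
  }
  withSeed(seed, {
    if (pSc > 0)
      out[] <- stats::rpois(length(out), pmax(out, 0) * pSc) / pSc
    if (gSd > 0)
      out <- out + stats::rnorm(length(out), 0, gSd)
  })
  VolumeSeries(array(out, c(shape, nt)), voxelSize = voxelSize,
               frameRate = truth@frameRate, probe = truth@probe,
               provenance = sprintf("synthetic render (seed %d)", seed))
}
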