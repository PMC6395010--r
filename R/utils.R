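# Shared numerical helpers: seeded RNG scoping, rigid shifting, running box
# means, FFT convolution, and the assignment solver used to match recovered
# components to ground-truth sources.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Flatten a (x,y,z,t) array into voxels x frames and back.
flattenVolumes <- function(arr) {
  d <- dim(arr)
  dim(arr) <- c(prod(d[1:3]), d[4])
  arr
}

foldVolumes <- function(mat, spatialDim) {
  array(mat, c(spatialDim, ncol(mat)))
}

#' Shift a 3D field by a rigid translation
#'
#' Pull-back resampling: \code{out[i] = field[i - shift]}. Integer shifts are
#' exact copies; fractional shifts use trilinear interpolation. Out-of-range
#' samples are clamped to the nearest edge voxel (no data are fabricated
#' beyond the border value).
#'
#' @param field 3D numeric array.
#' @param shift numeric length 3, shift in voxels along (x, y, z).
#' @return shifted 3D array of the same dimensions.
#' @export
shift3d <- function(field, shift) {
  stopifnot(length(dim(field)) == 3L, length(shift) == 3L, all(is.finite(shift)))
  d <- dim(field)
  if (all(shift == round(shift))) {
    s <- as.integer(round(shift))
    idx <- lapply(1:3, function(a) pmin(pmax(seq_len(d[a]) - s[a], 1L), d[a]))
    return(field[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- floor(shift)
  fr <- shift - lo
  out <- array(0, d)
  # trilinear: blend the 8 integer-shifted corners
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
    if (w == 0) next
    s <- as.integer(lo + c(cx, cy, cz))
    idx <- lapply(1:3, function(a) pmin(pmax(seq_len(d[a]) - s[a], 1L), d[a]))
    out <- out + w * field[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

# Centered running box mean along the time dimension of a voxels x frames
# matrix. Odd window: plain centered box. Even window: standard centered
# even-order moving average (the mean of the two length-w windows offset by
# one frame, i.e. half weights on the extreme frames). Edges use shrinking
# (truncated) windows; nothing is padded.
boxMeanTime <- function(mat, window) {
  nt <- ncol(mat)
  window <- as.integer(window)
  stopifnot(window >= 1, window <= nt)
  cs <- matrix(0, nrow(mat), nt + 1L)
  for (t in seq_len(nt)) cs[, t + 1L] <- cs[, t] + mat[, t]
  rangeMean <- function(a, b) {
    a <- pmax(a, 1L); b <- pmin(b, nt)
    sweep(cs[, b + 1L, drop = FALSE] - cs[, a, drop = FALSE], 2, b - a + 1L, "/")
  }
  i <- seq_len(nt)
  if (window %% 2L == 1L) {
    h <- (window - 1L) %/% 2L
    rangeMean(i - h, i + h)
  } else {
    h <- window %/% 2L
    (rangeMean(i - h, i + h - 1L) + rangeMean(i - h + 1L, i + h)) / 2
  }
}

# 2D circular convolution via FFT. Kernel is given as a small matrix centered
# on its middle element; it is zero-padded and rolled so the center acts as
# the origin. Used by the light field forward/adjoint operators, where the
# periodic boundary makes the adjoint exact.
kernelFFT <- function(kernel, dimXY) {
  kd <- dim(kernel)
  big <- matrix(0, dimXY[1], dimXY[2])
  big[seq_len(kd[1]), seq_len(kd[2])] <- kernel
  # roll so kernel center lands on (1,1)
  cx <- (kd[1] + 1L) %/% 2L
  cy <- (kd[2] + 1L) %/% 2L
  big <- big[c(cx:dimXY[1], seq_len(cx - 1L)), , drop = FALSE]
  big[, c(cy:dimXY[2], seq_len(cy - 1L)), drop = FALSE]
  # (fft taken by caller)
}

conv2circ <- function(img, kfft) {
  Re(fft(fft(img) * kfft, inverse = TRUE)) / length(img)
}

# circular integer roll of a matrix
roll2d <- function(m, sx, sy) {
  d <- dim(m)
  sx <- ((sx %% d[1]) + d[1]) %% d[1]
  sy <- ((sy %% d[2]) + d[2]) %% d[2]
  if (sx) m <- m[c((d[1] - sx + 1L):d[1], seq_len(d[1] - sx)), , drop = FALSE]
  if (sy) m <- m[, c((d[2] - sy + 1L):d[2], seq_len(d[2] - sy)), drop = FALSE]
  m
}

#' Solve the linear assignment problem
#'
#' Minimum-cost one-to-one assignment of rows to columns by the shortest
#' augmenting path algorithm (O(n^3)). Rows may be fewer than columns.
#'
#' @param cost numeric matrix (nr x nc, nr <= nc) of assignment costs.
#' @return integer vector of length nr: the column assigned to each row.
#' @export
solveAssignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc, all(is.finite(cost)))
  # potentials + augmenting paths (Jonker-Volgenant style, dense)
  INF <- Inf
  u <- numeric(nr + 1L); v <- numeric(nc + 1L)
  p <- integer(nc + 1L)        # p[j]: row assigned to column j (0 = free)
  way <- integer(nc + 1L)
  for (i in seq_len(nr)) {
    p[nc + 1L] <- i
    j0 <- nc + 1L
    minv <- rep(INF, nc + 1L)
    used <- rep(FALSE, nc + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(nc)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(nc + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == nc + 1L) break
    }
  }
  assign <- integer(nr)
  for (j in seq_len(nc)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

# cosine similarity between two vectors
cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match recovered components to ground-truth sources
#'
#' Hungarian assignment of ground-truth sources to extracted components,
#' maximizing the mean of map cosine similarity and trace Pearson
#' correlation. Used by the end-to-end recovery checks.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param cs a \linkS4class{ComponentSet}.
#' @param detrendWindowS if the movie was detrended before extraction, the
#'   same centered box filter (in seconds, at the truth frame rate) is
#'   applied to the ground-truth traces before correlating: signal removed
#'   by design cannot be recovered, so like is compared with like.
#' @return data.frame with one row per source: matched component index, map
#'   cosine similarity, and trace Pearson correlation.
#' @export
matchSources <- function(truth, cs, detrendWindowS = NULL) {
  s <- dim(truth@sourceMaps)[4]
  k <- nComponents(cs)
  stopifnot(s <= k)
  tm <- flattenVolumes(truth@sourceMaps)
  cm <- flattenVolumes(cs@maps)
  truthTraces <- truth@sourceTraces
  if (!is.null(detrendWindowS)) {
    w <- round(detrendWindowS * truth@frameRate)
    tt <- t(truthTraces)
    truthTraces <- t(tt - boxMeanTime(tt, w))
  }
  score <- matrix(0, s, k)
  for (i in seq_len(s)) {
    ti <- tm[, i]
    tt <- truthTraces[, i]
    ttv <- stats::sd(tt) > 0
    for (j in seq_len(k)) {
      cj <- cosineSim(ti, cm[, j])
      rj <- if (ttv && stats::sd(cs@traces[, j]) > 0)
        stats::cor(tt, cs@traces[, j]) else 0
      score[i, j] <- (cj + rj) / 2
    }
  }
  pick <- solveAssignment(1 - score)
  data.frame(
    source = seq_len(s),
    component = pick,
    mapCosine = vapply(seq_len(s), function(i) cosineSim(tm[, i], cm[, pick[i]]),
                       numeric(1)),
    traceR = vapply(seq_len(s), function(i) {
      tt <- truthTraces[, i]
      if (stats::sd(tt) == 0) return(NA_real_)
      stats::cor(tt, cs@traces[, pick[i]])
    }, numeric(1))
  )
}
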