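# Landmark affine registration, component-to-region sorting, 3D object
# counting, region presence, and the automatic artifact-classification rules
# (components smeared over many regions and/or fragmented into many objects).

#' Least-squares affine from matched landmarks
#'
#' Finds the 3x4 affine minimizing the sum of squared distances between the
#' transformed moving landmarks and the fixed landmarks, matched by name.
#' Requires at least 4 shared, non-coplanar landmarks.
#'
#' @param moving,fixed numeric n x 3 matrices of physical coordinates (um)
#'   with landmark names as rownames.
#' @return An \linkS4class{AffineTransform} with the residual RMS recorded.
#' @export
landmarkAffine <- function(moving, fixed) {
  shared <- intersect(rownames(moving), rownames(fixed))
  if (length(shared) < 4)
    stop("need at least 4 shared landmark names (found ", length(shared), ")")
  M <- moving[shared, , drop = FALSE]
  F <- fixed[shared, , drop = FALSE]
  ctr <- sweep(M, 2, colMeans(M))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-9 * sv[1])
    stop("landmarks are coplanar: affine is underdetermined")
  Xd <- cbind(M, 1)
  B <- qr.solve(Xd, F)          # 4 x 3
  A <- t(B)                     # 3 x 4
  res <- Xd %*% B - F
  rms <- sqrt(mean(rowSums(res^2)))
  new("AffineTransform", matrix = A, residualRms = rms)
}

#' Apply an affine transform to a 3D field
#'
#' Pull-back resampling onto a target grid: for each target voxel the inverse
#' transform locates the source position, which is sampled with trilinear
#' interpolation (continuous fields) or nearest neighbor (integer label
#' fields). Positions outside the source grid map to 0.
#'
#' @param field 3D array (continuous or integer labels).
#' @param transform an \linkS4class{AffineTransform} mapping moving (source)
#'   to fixed (target) physical coordinates.
#' @param voxelSize source voxel pitch (um).
#' @param targetDim target grid dimensions (default: source dims).
#' @param targetVoxelSize target voxel pitch (default: source pitch).
#' @param method \code{"auto"} (nearest for integer-valued fields, trilinear
#'   otherwise), \code{"trilinear"} or \code{"nearest"}.
#' @return resampled 3D array on the target grid.
#' @export
applyTransform <- function(field, transform, voxelSize,
                           targetDim = dim(field),
                           targetVoxelSize = voxelSize,
                           method = c("auto", "trilinear", "nearest")) {
  stopifnot(is(transform, "AffineTransform"), length(dim(field)) == 3L)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (all(field == round(field))) "nearest" else "trilinear"
  A <- transform@matrix
  Alin <- A[, 1:3]
  if (abs(det(Alin)) <= 1e-9) stop("degenerate transform")
  Ainv <- solve(Alin)
  d <- as.integer(targetDim)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  # physical target coords (0-based voxel convention)
  P <- cbind((g$x - 1) * targetVoxelSize[1],
             (g$y - 1) * targetVoxelSize[2],
             (g$z - 1) * targetVoxelSize[3])
  Q <- t(Ainv %*% (t(P) - A[, 4]))          # source physical coords
  src <- sweep(Q, 2, voxelSize, "/") + 1    # source voxel coords (1-based)
  sd3 <- dim(field)
  if (method == "nearest") {
    idx <- round(src)
    ok <- idx[, 1] >= 1 & idx[, 1] <= sd3[1] &
      idx[, 2] >= 1 & idx[, 2] <= sd3[2] &
      idx[, 3] >= 1 & idx[, 3] <= sd3[3]
    out <- numeric(nrow(idx))
    out[ok] <- field[idx[ok, , drop = FALSE]]
  } else {
    lo <- floor(src)
    fr <- src - lo
    out <- numeric(nrow(src))
    okAll <- src[, 1] >= 1 & src[, 1] <= sd3[1] &
      src[, 2] >= 1 & src[, 2] <= sd3[2] &
      src[, 3] >= 1 & src[, 3] <= sd3[3]
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
        (if (cy) fr[, 2] else 1 - fr[, 2]) *
        (if (cz) fr[, 3] else 1 - fr[, 3])
      idx <- cbind(pmin(pmax(lo[, 1] + cx, 1), sd3[1]),
                   pmin(pmax(lo[, 2] + cy, 1), sd3[2]),
                   pmin(pmax(lo[, 3] + cz, 1), sd3[3]))
      out <- out + w * field[idx]
    }
    out[!okAll] <- 0
  }
  array(out, d)
}

# inverse of an AffineTransform
#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
  A <- transform@matrix
  Ainv <- solve(A[, 1:3])
  new("AffineTransform", matrix = cbind(Ainv, -Ainv %*% A[, 4]),
      residualRms = numeric(0))
}

#' Sort components into atlas regions
#'
#' Assigns each component to the region with the highest mean of the map's
#' positive part within the region mask. Ties are broken by the larger count
#' of supra-zero voxels in the region, then by the lower label. Components
#' with no positive weight inside any region are labeled
#' \code{"unassigned"}.
#'
#' @param cs a \linkS4class{ComponentSet}.
#' @param atlas a \linkS4class{RegionAtlas} on the component grid.
#' @return the \linkS4class{ComponentSet} with \code{regionLabel} filled.
#' @export
sortByRegion <- function(cs, atlas) {
  stopifnot(is(cs, "ComponentSet"), is(atlas, "RegionAtlas"))
  if (!all(dim(cs@maps)[1:3] == dim(atlas@labels)))
    stop("atlas must be resampled to the component grid first")
  labs <- as.integer(atlas@labels)
  regions <- sort(unique(labs[labs > 0]))
  M <- flattenVolumes(cs@maps)
  for (i in seq_len(ncol(M))) {
    pos <- pmax(M[, i], 0)
    means <- vapply(regions, function(r) mean(pos[labs == r]), numeric(1))
    if (all(means <= 0)) {
      cs@regionLabel[i] <- "unassigned"
      next
    }
    best <- which(means == max(means))
    if (length(best) > 1) {
      counts <- vapply(regions[best],
                       function(r) sum(pos[labs == r] > 0), numeric(1))
      best <- best[counts == max(counts)]
      best <- best[1]   # lowest label among remaining ties
    }
    cs@regionLabel[i] <- unname(atlas@regionNames[as.character(regions[best])])
  }
  cs
}

#' Count connected objects in a binary 3D mask
#'
#' Connected-component count under 6-, 18- or 26-connectivity (default 26,
#' the standard for 3D blob counting).
#'
#' @param mask logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer object count.
#' @export
countObjects <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 18, 26))
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0) return(0L)
  d <- dim(mask)
  ids <- array(0L, d)
  ids[mask] <- seq_len(n)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "6" = offs[m == 1, ],
                 "18" = offs[m <= 2, ],
                 "26" = offs)
  # half neighborhood suffices for undirected edges
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
               (offs$dy == 0 & offs$dx > 0))), ]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    xa <- seq_len(d[1] - abs(o[1])); ya <- seq_len(d[2] - abs(o[2]))
    za <- seq_len(d[3] - abs(o[3]))
    xb <- xa + abs(o[1]); yb <- ya + abs(o[2]); zb <- za + abs(o[3])
    if (o[1] < 0) { tmp <- xa; xa <- xb; xb <- tmp }
    if (o[2] < 0) { tmp <- ya; ya <- yb; yb <- tmp }
    if (o[3] < 0) { tmp <- za; za <- zb; zb <- tmp }
    a <- ids[xa, ya, za, drop = FALSE]
    b <- ids[xb, yb, zb, drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(a[both], b[both])
  }
  if (!length(edges)) return(as.integer(n))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Regions in which a map is present
#'
#' A region counts as "present" in a map when the fraction of its voxels
#' exceeding the map's k-sigma threshold (SD about zero, positive side) is
#' above \code{fraction}. The presence criterion itself is a package
#' convention; both the threshold and the fraction are configurable.
#'
#' @param map 3D component map.
#' @param atlas a \linkS4class{RegionAtlas} on the same grid.
#' @param k threshold in SD units.
#' @param fraction minimum supra-threshold voxel fraction (default 0.5\%).
#' @return character vector of region names present.
#' @export
regionPresence <- function(map, atlas, k = 3, fraction = 0.005) {
  stopifnot(is(atlas, "RegionAtlas"))
  if (!all(dim(map) == dim(atlas@labels))) stop("grids must match")
  s <- sqrt(mean(map^2))
  if (s == 0) return(character(0))
  supra <- map >= k * s
  labs <- as.integer(atlas@labels)
  regions <- sort(unique(labs[labs > 0]))
  present <- vapply(regions, function(r) {
    inR <- labs == r
    sum(supra[inR]) / sum(inR) > fraction
  }, logical(1))
  unname(atlas@regionNames[as.character(regions[present])])
}

#' Automatic artifact classification
#'
#' Flags components that are smeared across many regions (more than
#' \code{maxRegions} regions present) and/or fragmented into many separate
#' objects (more than \code{maxObjects} connected components of the k-sigma
#' mask). Under rule \code{"or"} (default) either violation flags the
#' component; rule \code{"and"} requires both. Components already flagged
#' \code{"manual"} are never overridden. The per-component region and object
#' counts are recorded in the returned set.
#'
#' @param cs a \linkS4class{ComponentSet}.
#' @param atlas a \linkS4class{RegionAtlas} on the component grid.
#' @param rule \code{"or"} or \code{"and"}.
#' @param maxRegions region-count threshold (flag when count > this).
#' @param maxObjects object-count threshold (flag when count > this).
#' @param k sigma threshold for masks and presence.
#' @param fraction presence voxel fraction.
#' @param connectivity object-counting connectivity.
#' @return the annotated \linkS4class{ComponentSet}.
#' @export
classifyArtifacts <- function(cs, atlas, rule = c("or", "and"),
                              maxRegions = 5, maxObjects = 200, k = 3,
                              fraction = 0.005, connectivity = 26) {
  stopifnot(is(cs, "ComponentSet"), is(atlas, "RegionAtlas"))
  rule <- match.arg(rule)
  M <- flattenVolumes(cs@maps)
  d3 <- dim(cs@maps)[1:3]
  for (i in seq_len(ncol(M))) {
    map <- array(M[, i], d3)
    s <- sqrt(mean(map^2))
    mask <- if (s > 0) map >= k * s else array(FALSE, d3)
    nObj <- countObjects(mask, connectivity)
    nReg <- length(regionPresence(map, atlas, k, fraction))
    cs@nObjects[i] <- as.integer(nObj)
    cs@nRegionsPresent[i] <- as.integer(nReg)
    if (cs@artifact[i] == "manual") next   # manual calls are never dropped
    manyReg <- nReg > maxRegions
    manyObj <- nObj > maxObjects
    hit <- if (rule == "or") manyReg || manyObj else manyReg && manyObj
    if (hit) cs@artifact[i] <- if (manyReg) "movement" else "noise"
  }
  cs@meta$artifactRule <- rule
  cs
}

#' Write an artifact classification report
#'
#' @param cs an annotated \linkS4class{ComponentSet}.
#' @param path TSV path.
#' @return invisibly, the report data.frame.
#' @export
writeClassificationReport <- function(cs, path) {
  df <- data.frame(
    component = seq_len(nComponents(cs)),
    region = cs@regionLabel,
    n_regions = cs@nRegionsPresent,
    n_objects = cs@nObjects,
    flag = cs@artifact,
    rule = cs@meta$artifactRule %||% NA_character_
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
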