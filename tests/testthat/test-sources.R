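# Source-extraction chain: variance normalization, PCA, shoulder detection,
# ICA unmixing, sign convention, ROI masks and time series.

test_that("variance normalization equalizes the noise floor", {
  set.seed(1)
  d <- c(6, 5, 4, 400)
  # iid unit-variance noise, no pre-SVD: output variances ~ 1
  vs <- VolumeSeries(array(rnorm(prod(d)), d), frameRate = 10)
  out <- varianceNormalize(vs, nPresvd = 0)
  vars <- apply(flat4(volData(out$volumes)), 1, var)
  expect_true(all(abs(vars - 1) < 0.1 + 3 * sqrt(2 / d[4])))
  # constant voxel excluded via the epsilon floor and counted
  X <- array(rnorm(prod(d)), d); X[1, 1, 1, ] <- 5
  outC <- varianceNormalize(VolumeSeries(X, frameRate = 10), nPresvd = 0)
  expect_gte(outC$nFloored, 1)
  # removing the top component leaves the noise variance, not the signal
  u <- rexp(prod(d[1:3])); v <- sin(2 * pi * (1:d[4]) / 50)
  Xr <- array(outer(10 * u, v), d) + array(rnorm(prod(d)), d)
  outR <- varianceNormalize(VolumeSeries(Xr, frameRate = 10), nPresvd = 1)
  expect_lt(max(outR$varianceMap), 2.5)   # signal variance would be >> this
  expect_gt(mean(outR$varianceMap), 0.5)
  cst <- VolumeSeries(array(2, c(3, 3, 2, 10)), frameRate = 10)
  expect_error(varianceNormalize(cst, nPresvd = 0), "constant")
})

test_that("PCA is an exact thin SVD", {
  # rank-2 movie: third singular value vanishes
  set.seed(2)
  d <- c(5, 4, 2, 30)
  u <- matrix(rnorm(prod(d[1:3]) * 2), ncol = 2)
  v <- matrix(rnorm(d[4] * 2), ncol = 2)
  vs <- VolumeSeries(array(u %*% t(v), d), frameRate = 10)
  sp <- pcaVolumes(vs)
  expect_lt(singularValues(sp)[3] / singularValues(sp)[1], 1e-8)
  # non-increasing for random input; reconstruction from all modes is exact
  vr <- VolumeSeries(array(rnorm(prod(d)), d), frameRate = 10)
  spr <- pcaVolumes(vr)
  expect_true(all(diff(singularValues(spr)) <= 1e-8))
  recon <- spr@spatialModes %*% (singularValues(spr)[seq_len(ncol(spr@spatialModes))] *
                                   t(spr@temporalModes))
  expect_equal(recon, flat4(volData(vr)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # 3-voxel x 2-frame matrix against the closed-form singular values:
  # X = [[0,1],[1,0],[1,1]] has X^T X eigenvalues 3 and 1
  X <- array(c(0, 1, 1, 1, 0, 1), c(3, 1, 1, 2))
  spx <- pcaVolumes(VolumeSeries(X, frameRate = 1))
  expect_equal(singularValues(spx), c(sqrt(3), 1), tolerance = 1e-10)
  expect_error(pcaVolumes(VolumeSeries(array(0, c(2, 2, 1, 1)),
                                       frameRate = 1)), "2 frames")
})

test_that("shoulder detection matches the exhaustive-scan oracle", {
  # flat spectrum: no shoulder
  expect_error(detectShoulder(rep(2, 10)), "no shoulder")
  # piecewise log-linear with normalized slopes -0.2 then -3: the -1
  # crossing falls at index 20 on a 28-point grid
  expect_identical(detectShoulder(piecewiseSpectrum()), 20L)
  expect_identical(shoulderOracle(piecewiseSpectrum()), 20L)
  # oracle equivalence on 100 seeded random decaying spectra
  set.seed(9)
  for (i in 1:100) {
    sv <- randomSpectrum()
    got <- tryCatch(detectShoulder(sv), error = function(e) NA_integer_)
    expect_identical(got, shoulderOracle(sv))
  }
  expect_error(detectShoulder(c(3, 2, 1)), "at least 4")
})

test_that("the double-the-shoulder rule is clamped to the rank", {
  expect_identical(chooseNComponents(30), 60L)
  expect_identical(chooseNComponents(30, rank = 45), 45L)
  expect_identical(chooseNComponents(1), 2L)
  expect_error(chooseNComponents(0), "shoulder")
})

test_that("spatial ICA unmixes disjoint sparse maps", {
  set.seed(3)
  d <- c(10, 8, 4, 300)
  nv <- prod(d[1:3])
  # 4 disjoint sparse maps with independent smooth traces
  maps <- matrix(0, nv, 4)
  blocks <- split(sample(nv, 80), rep(1:4, each = 20))
  for (s in 1:4) maps[blocks[[s]], s] <- runif(20, 0.5, 1)
  traces <- matrix(0, d[4], 4)
  for (s in 1:4)
    traces[, s] <- as.numeric(stats::filter(rnorm(d[4]), rep(1/5, 5),
                                            circular = TRUE))
  X <- maps %*% t(traces) + matrix(rnorm(nv * d[4], sd = 0.02), nv)
  vs <- VolumeSeries(array(X, d), frameRate = 10)
  sp <- pcaVolumes(vs, k = 8)
  cs <- runIca(sp, 4, seed = 5)
  # Hungarian matching of recovered maps to truth, cosine > 0.95
  cm <- flat4(cs@maps)
  score <- outer(1:4, 1:4, Vectorize(function(i, j)
    abs(sum(maps[, i] * cm[, j])) /
      sqrt(sum(maps[, i]^2) * sum(cm[, j]^2))))
  pick <- solveAssignment(1 - score)
  expect_true(all(score[cbind(1:4, pick)] > 0.95))
  # determinism given the seed
  cs2 <- runIca(sp, 4, seed = 5)
  expect_identical(cs@maps, cs2@maps)
  expect_identical(cs@traces, cs2@traces)
  # unmixing consistency: maps x (scale * traces) = rank-n truncation
  recon <- cm %*% (t(cs@traces) * cs@traceScale)
  trunc <- sp@spatialModes[, 1:4] %*% (singularValues(sp)[1:4] *
                                         t(sp@temporalModes[, 1:4]))
  expect_lt(max(abs(recon - trunc)) / max(abs(trunc)), 1e-6)
  # n = 1 spans the dominant subspace on rank-1 data
  X1 <- maps[, 1, drop = FALSE] %*% t(traces[, 1, drop = FALSE])
  vs1 <- VolumeSeries(array(X1, d), frameRate = 10)
  sp1 <- pcaVolumes(vs1, k = 2)
  cs1 <- runIca(sp1, 1, seed = 2)
  expect_gt(abs(cor(flat4(cs1@maps)[, 1], sp1@spatialModes[, 1])), 0.99)
  expect_error(runIca(sp, 100, seed = 1), "rank")
})

test_that("the sign convention flips pairs together and is idempotent", {
  maps <- array(0, c(4, 3, 2, 2))
  maps[, , , 1] <- c(rep(0.8, 12), rep(-0.2, 12))   # positive side dominates
  maps[, , , 2] <- c(rep(-0.8, 12), rep(0.2, 12))   # negative side dominates
  traces <- matrix(rnorm(20), 10, 2)
  cs <- new("ComponentSet", maps = maps, traces = traces,
            traceScale = c(1, 1), signFixed = FALSE,
            regionLabel = rep("unassigned", 2),
            artifact = rep("activity", 2),
            nRegionsPresent = rep(NA_integer_, 2),
            nObjects = rep(NA_integer_, 2), meta = list())
  fx <- fixSigns(cs)
  expect_identical(fx@maps[, , , 1], cs@maps[, , , 1])     # unchanged
  expect_identical(fx@maps[, , , 2], -cs@maps[, , , 2])    # flipped back
  expect_identical(fx@traces[, 2], -cs@traces[, 2])        # trace follows map
  # involution on the negated map gives the same fixed map
  expect_identical(fx@maps[, , , 2], fx@maps[, , , 1] * 1)
  # idempotence
  fx2 <- fixSigns(fx)
  expect_identical(fx2@maps, fx@maps)
  expect_identical(fx2@traces, fx@traces)
})

test_that("k-sigma masks follow the Gaussian tail and closed forms", {
  # all-zero-except-one-voxel map: that voxel alone survives
  m <- array(0, c(5, 5, 4)); m[2, 3, 1] <- 10
  sdExpected <- sqrt(mean(m^2))        # SD about zero of the constructed map
  expect_gt(10, 3 * sdExpected)
  mask <- zscoreThresholdMask(m, k = 3)
  expect_equal(sum(mask@weights > 0), 1)
  expect_equal(mask@weights[2, 3, 1], 10)
  # iid standard normal, k = 3: surviving fraction ~ pnorm upper tail
  set.seed(8)
  n <- 40^3
  g <- array(rnorm(n), c(40, 40, 40))
  mk <- zscoreThresholdMask(g, k = 3)
  p <- 1 - pnorm(3)
  frac <- sum(mk@weights > 0) / n
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n))
  # k = 0 keeps exactly the positive part
  m0 <- zscoreThresholdMask(g, k = 0)
  expect_equal(m0@weights[g > 0], g[g > 0], ignore_attr = TRUE)
  expect_true(all(m0@weights[g < 0] == 0))
  expect_error(zscoreThresholdMask(array(0, c(2, 2, 2))), "standard deviation")
})

test_that("ROI time series are the stated weighted averages", {
  d <- c(3, 2, 1, 5)
  X <- array(rnorm(prod(d)), d)
  vs <- VolumeSeries(X, frameRate = 10)
  w <- array(1, d[1:3])
  mask <- new("RoiMask", weights = w, component = 1L, thresholdK = 0)
  expect_equal(roiTimeseries(vs, mask),
               apply(X, 4, mean))                      # plain spatial mean
  w1 <- array(0, d[1:3]); w1[2, 1, 1] <- 1
  m1 <- new("RoiMask", weights = w1, component = 1L, thresholdK = 0)
  expect_equal(roiTimeseries(vs, m1), X[2, 1, 1, ])    # single voxel
  w2 <- array(0, d[1:3]); w2[1, 1, 1] <- 1; w2[3, 2, 1] <- 3
  m2 <- new("RoiMask", weights = w2, component = 1L, thresholdK = 0)
  expect_equal(roiTimeseries(vs, m2),
               (X[1, 1, 1, ] + 3 * X[3, 2, 1, ]) / 4)  # hand arithmetic
  small <- VolumeSeries(array(1, c(2, 2, 2, 3)), frameRate = 1)
  expect_error(roiTimeseries(small, m2), "grids differ")
})

test_that("the full chain recovers planted sources end to end", {
  atl <- makeAtlas(c(32, 16, 8), 4, seed = 21)
  tr <- makeGroundTruth(atl, 6, durationS = 20, frameRateHz = 100, seed = 22)
  mv <- renderMovie(tr, baseline = makeBaseline(atl, 100, seed = 23),
                    noise = list(gaussianSd = 2), seed = 24)
  vn <- varianceNormalize(detrend(mv, 15), nPresvd = 2)
  sp <- pcaVolumes(vn$volumes, k = 40)
  n <- chooseNComponents(detectShoulder(sp), 40)
  cs <- suppressWarnings(fixSigns(runIca(sp, n, seed = 25)))
  m <- matchSources(tr, cs, detrendWindowS = 15)
  expect_gte(sum(m$mapCosine > 0.7 & m$traceR > 0.7), 5)
})
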