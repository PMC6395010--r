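# Preprocessing chain contracts.

test_that("motion correction recovers imposed rigid shifts", {
  atl <- tinyAtlas()
  tr <- makeGroundTruth(atl, 3, durationS = 6, frameRateHz = 20, seed = 2)
  bg <- makeBaseline(atl, 100, seed = 4)
  # already-aligned movie: estimated shifts all ~0
  mv0 <- renderMovie(tr, baseline = bg, motionAmpVoxels = 0,
                     noise = list(gaussianSd = 1), seed = 3)
  mc0 <- motionCorrect(mv0)
  expect_true(all(abs(mc0$motion@translation) <= 0.25))
  # imposed shifts up to +/-2 voxels recovered within 0.5 voxel RMS
  mv <- renderMovie(tr, baseline = bg, motionAmpVoxels = 2,
                    noise = list(gaussianSd = 1), seed = 3)
  mc <- motionCorrect(mv)
  err <- mc$motion@translation - 2 * tr@motionPath
  expect_lt(sqrt(mean(err^2)), 0.5)
  # correction reduces frame-to-reference RMS displacement by >= 75%
  # (ground-truth motion available from the generator)
  expect_lt(sqrt(mean(err^2)), 0.25 * sqrt(mean((2 * tr@motionPath)^2)))
  # all-constant frames: warning path, zero shift, finite output
  cst <- VolumeSeries(array(5, c(8, 8, 4, 3)), frameRate = 10)
  expect_warning(mcc <- motionCorrect(cst), "constant")
  expect_true(all(mcc$motion@translation == 0))
  expect_true(all(is.finite(volData(mcc$volumes))))
})

test_that("sign inversion is guarded, recorded, and involutive", {
  vs <- VolumeSeries(array(5, c(4, 4, 2, 3)), probe = "arclight")
  out <- invertSign(vs)
  expect_true(all(volData(out) == -5))
  expect_identical(volData(invertSign(out)), volData(vs))
  expect_match(provenance(out), "sign", all = FALSE)
  vg <- VolumeSeries(array(1, c(4, 4, 2, 3)), probe = "gcamp6f")
  expect_error(invertSign(vg), "arclight")
  expect_silent(invertSign(vg, force = TRUE))
})

test_that("detrending removes constants, ramps and exponential bleach", {
  nt <- 200; rate <- 10
  cst <- VolumeSeries(array(7, c(3, 3, 2, nt)), frameRate = rate)
  expect_true(all(volData(detrend(cst, 5)) == 0))
  # centered box average of a line equals the line at interior frames
  ramp <- array(rep(seq_len(nt), each = 4), c(2, 2, 1, nt))
  dr <- volData(detrend(VolumeSeries(ramp, frameRate = rate), 5))
  w <- 50
  interior <- (w + 1):(nt - w)
  expect_equal(max(abs(dr[1, 1, 1, interior])), 0, tolerance = 1e-10)
  # 13%/30s exponential bleach: residual trend slope reduced > 90%
  # (slopes from a least-squares regression oracle)
  nt <- 1200; rate <- 20
  tSec <- (0:(nt - 1)) / rate
  bleach <- 100 * exp(log(1 - 0.13) / 30 * tSec)
  vs <- VolumeSeries(array(rep(bleach, each = 16), c(4, 2, 2, nt)),
                     frameRate = rate)
  dt <- detrend(vs, 15)
  s0 <- abs(stats::coef(stats::lm(bleach ~ tSec))[2])
  s1 <- abs(stats::coef(stats::lm(colMeans(flat4(volData(dt))) ~ tSec))[2])
  expect_lt(s1 / s0, 0.1)
  # detrend o detrend ~ detrend on smooth inputs: away from the shrinking
  # edge windows, the second pass leaves under 1e-6 of the original trend
  dt2 <- detrend(dt, 15)
  int <- 301:(nt - 300)
  m2 <- colMeans(flat4(volData(dt2)))[int]
  s2 <- abs(stats::coef(stats::lm(m2 ~ tSec[int]))[2])
  expect_lt(s2, 1e-6 * s0)
  expect_error(detrend(vs, 1000), "longer than the recording")
})

test_that("recursive denoising follows the stated recursion", {
  vs <- VolumeSeries(array(rnorm(4 * 4 * 2 * 20), c(4, 4, 2, 20)),
                     frameRate = 10)
  expect_identical(volData(kalmanDenoise(vs, gain = 1)), volData(vs))
  cstv <- VolumeSeries(array(3, c(2, 2, 1, 10)), frameRate = 10)
  expect_equal(volData(kalmanDenoise(cstv, 0.3)), volData(cstv))
  # unit step at t = 4, gain 0.5: hand-iterated recursion
  step <- VolumeSeries(array(rep(c(0, 0, 0, rep(1, 5)), each = 1),
                             c(1, 1, 1, 8)), frameRate = 10)
  expect_equal(as.numeric(volData(kalmanDenoise(step, 0.5))),
               c(0, 0, 0, 0.5, 0.75, 0.875, 0.9375, 0.96875))
  expect_error(kalmanDenoise(vs, 0), "gain")
  expect_error(kalmanDenoise(vs, 1.5), "gain")
})

test_that("SVD subtraction removes the chosen rank-1 terms", {
  set.seed(4)
  d <- c(6, 5, 3, 40)
  u1 <- rnorm(prod(d[1:3])); v1 <- rnorm(d[4])
  contam <- array(outer(u1, 5 * v1), d)
  noise <- array(rnorm(prod(d), sd = 0.05), d)
  vs <- VolumeSeries(contam + noise, frameRate = 10)
  # empty set: bit-exact identity
  expect_identical(volData(svdMotionRemoval(vs, integer(0))$volumes),
                   volData(vs))
  out <- svdMotionRemoval(vs, 1L)
  R <- flat4(volData(out$volumes))
  # residual orthogonal to the removed temporal vector
  sp <- svd(flat4(volData(vs)), nu = 0, nv = 1)
  expect_lt(max(abs(R %*% sp$v[, 1])), 1e-8)
  # total variance never increases
  expect_lte(sum(R^2), sum(volData(vs)^2))
  expect_error(svdMotionRemoval(VolumeSeries(array(numeric(0), c(0, 0, 0, 0)),
                                             frameRate = 1)), "empty")
})

test_that("dF/F matches closed forms and masks bad baselines", {
  cst <- VolumeSeries(array(4, c(3, 3, 2, 10)), frameRate = 10)
  expect_true(all(volData(dff(cst)) == 0))
  # F = 2*F0 at one frame
  x <- rep(10, 20); x[7] <- 20
  vs <- VolumeSeries(array(rep(x, each = 1), c(1, 1, 1, 20)), frameRate = 10)
  out <- dff(vs, baseline = "percentile", percentile = 10)
  expect_equal(volData(out)[1, 1, 1, 7], 1.0)
  # recovered peak dF/F = amplitude / baseline within 1%
  kern <- kernelTaps(makeKernel("gcamp6f", 20))
  tr <- c(numeric(10), 25 * kern, numeric(10))
  vs2 <- VolumeSeries(array(100 + tr, c(1, 1, 1, length(tr))),
                      frameRate = 20)
  out2 <- dff(vs2, baseline = "percentile", percentile = 10)
  expect_equal(max(volData(out2)), 25 / 100, tolerance = 0.01)
  # non-positive baseline voxels are masked and reported
  bad <- VolumeSeries(array(rep(c(0, 5), 10), c(2, 1, 1, 10)),
                      frameRate = 10)
  expect_message(ob <- dff(bad), "masked")
  expect_true(all(volData(ob)[1, 1, 1, ] == 0))
})

test_that("high-pass keeps fast activity and removes slow", {
  dc <- VolumeSeries(array(3, c(2, 2, 1, 50)), frameRate = 200)
  expect_equal(max(abs(volData(highpass(dc)))), 0)
  # frequency response vs the box-filter attenuation (sd-based oracle)
  rate <- 200; nt <- 2000
  tt <- (0:(nt - 1)) / rate
  kept <- vapply(c(1, 40), function(f) {
    x <- sin(2 * pi * f * tt)
    v <- VolumeSeries(array(x, c(1, 1, 1, nt)), frameRate = rate)
    stats::sd(volData(highpass(v, 0.1))[1, 1, 1, ]) / stats::sd(x)
  }, numeric(1))
  expect_lt(1 - kept[1], 1)      # definitions: kept = 1 - attenuation
  expect_gt(1 - kept[1], 0.95)   # 1 Hz attenuated > 95%
  expect_lt(1 - kept[2], 0.30)   # 40 Hz attenuated < 30%
  # 100 ms at 200 Hz is a 20-frame window
  v <- VolumeSeries(array(rnorm(200), c(1, 1, 1, 200)), frameRate = 200)
  expect_match(provenance(highpass(v, 0.1)), "20 frames", all = FALSE)
  slow <- VolumeSeries(array(1, c(1, 1, 1, 10)), frameRate = 5)
  expect_error(highpass(slow, 0.1), "fewer than 2 frames")
})

test_that("behavior alignment warps and resamples correctly", {
  b <- makeBehavior(30, 100, seed = 6)
  # equal rates, zero drift: identity
  a0 <- alignBehavior(b, nFrames(b), 100, driftMsPerMin = 0)
  expect_identical(behaviorState(a0), behaviorState(b))
  expect_equal(a0@flowLeft, b@flowLeft)
  # closed-form index mapping under 30 ms/min drift over 60 s
  ramp <- new("BehaviorTrace", frameRate = 100,
              state = factor(rep("walk", 6000),
                             levels = c("rest", "walk", "groom")),
              flowLeft = seq(0, 59.99, by = 0.01), flowRight = numeric(6000))
  al <- alignBehavior(ramp, 6000, 100, driftMsPerMin = 30)
  j <- 6000
  tf <- (j - 1) / 100
  expected <- tf / (1 + 30 / 60000)   # behavior time read 30 ms/min early
  expect_equal(al@flowLeft[j], expected, tolerance = 1e-6)
  expect_lt(al@flowLeft[j], ramp@flowLeft[j])   # maps ~30 ms earlier
  # 100 Hz behavior onto a 200 Hz grid: each state appears on 2 frames
  up <- alignBehavior(b, 2 * nFrames(b) - 1, 200, driftMsPerMin = 0)
  s <- as.character(behaviorState(up))
  expect_identical(s[seq(1, length(s), by = 2)],
                   as.character(behaviorState(b)))
  expect_error(alignBehavior(b, 100, 100, driftMsPerMin = 1e5), "drift")
})

test_that("concatenation checks fields and records boundaries", {
  a <- VolumeSeries(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)))
  b <- VolumeSeries(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)))
  expect_identical(volData(concatVolumes(list(a))), volData(a))
  ab <- concatVolumes(list(a, b))
  expect_equal(nFrames(ab), 20)
  expect_match(provenance(ab), "boundaries at 10", all = FALSE)
  bBad <- VolumeSeries(array(1, c(4, 4, 2, 5)), voxelSize = c(1, 1, 1))
  expect_error(concatVolumes(list(a, bBad)), "voxelSize")
  bBad2 <- VolumeSeries(array(1, c(4, 4, 2, 5)), probe = "gfp")
  expect_error(concatVolumes(list(a, bBad2)), "probe")
})

test_that("z-slab reduction follows the greedy PSF-height partition", {
  d <- c(4, 3, 10, 6)
  vs <- VolumeSeries(array(rnorm(prod(d)), d), voxelSize = c(3, 3, 6))
  # uniform profile of one layer thickness: identity in z
  ident <- zslabReduce(vs, rep(6, 10))
  expect_equal(volData(ident)[, , , ], volData(vs)[, , , ],
               ignore_attr = TRUE)
  # equal-thickness slabs preserve the global mean exactly
  half <- zslabReduce(vs, rep(12, 10))
  expect_equal(mean(volData(half)), mean(volData(vs)), tolerance = 1e-12)
  # greedy partition oracle: (6,6,12,12,12,12,24,...) um on 6-um layers
  prof <- c(6, 6, 12, 12, 12, 12, 24, 24, 24, 24)
  red <- zslabReduce(vs, prof)
  slabs <- attr(volData(red), "slabs")
  expect_equal(vapply(slabs, length, integer(1)), c(1, 1, 2, 2, 4))
  expect_error(zslabReduce(vs, rep(-1, 10)), "positive")
})
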