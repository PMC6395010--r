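# Indicator kernels, regressors, correlation statistics, condition and
# stimulus maps, responsive-component counts and two-color rendering.

test_that("indicator kernels peak at the probe rise time", {
  k <- makeKernel("gcamp6f", 100)
  expect_lt(abs((which.max(kernelTaps(k)) - 1) / 100 - 0.15), 0.01)
  k2 <- makeKernel("arclight", 200)
  expect_lt(abs((which.max(kernelTaps(k2)) - 1) / 200 - 0.10), 0.005)
  expect_true(all(kernelTaps(k) >= 0))
  expect_equal(max(kernelTaps(k)), 1)
  expect_error(makeKernel("gcamp6f", 100, decayS = -1), "decayS")
  expect_error(makeKernel("gcamp6f", 5), "frame rate")
})

test_that("regressors are causal convolutions", {
  k <- makeKernel("gcamp6f", 50)
  expect_equal(buildRegressor(numeric(100), k), numeric(100))
  imp <- numeric(400); imp[1] <- 1
  out <- buildRegressor(imp, k)
  expect_equal(out[seq_along(kernelTaps(k))], kernelTaps(k),
               tolerance = 1e-10)
  expect_true(all(abs(out[-seq_along(kernelTaps(k))]) < 1e-10))
  set.seed(3)
  x <- rnorm(200)
  expect_equal(buildRegressor(x, k), convOracle(x, kernelTaps(k)),
               tolerance = 1e-10)
  expect_error(buildRegressor(x, k, frameRateHz = 100), "does not match")
})

test_that("correlation statistics behave as defined", {
  x <- rnorm(100)
  expect_equal(pearsonR(x, x), 1)
  expect_equal(pearsonR(x, -x), -1)
  # sine and cosine over whole periods are orthogonal
  tt <- seq(0, 4 - 1e-9, by = 0.01)
  expect_lt(abs(pearsonR(sin(2 * pi * tt), cos(2 * pi * tt))), 1e-6)
  expect_error(pearsonR(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearsonR(x, rnorm(99)), "equal length")
  expect_equal(rSquared(x, 2 * x), 1)
  expect_equal(rSquared(x, -x), 1)
  set.seed(4)
  expect_lt(rSquared(rnorm(1e4), rnorm(1e4)), 0.01)   # null sampling
})

test_that("cross-correlation lag is recovered with its sign convention", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(3000), rep(1 / 10, 10),
                                circular = TRUE))
  expect_equal(xcorrPeakLag(x, x, 100, 0.3), 0)
  y <- c(numeric(7), x)[1:3000]     # y follows x by 7 frames at 100 Hz
  expect_lt(abs(xcorrPeakLag(x, y, 100, 0.5) - 0.070), 0.005)
  expect_lt(abs(xcorrPeakLag(y, x, 100, 0.5) + 0.070), 0.005)
  expect_error(xcorrPeakLag(x, x, 100, 50), "too large")
})

test_that("condition maps difference voxel means and antisymmetrize", {
  d <- c(4, 3, 2, 20)
  X <- array(rnorm(prod(d)), d)
  X[2, 1, 1, 1:10] <- 0.5; X[2, 1, 1, 11:20] <- 0.2
  vs <- VolumeSeries(X, frameRate = 10)
  cm <- conditionDifferenceMap(vs, 1:10, 11:20, "walk", "rest")
  expect_equal(cm@values[2, 1, 1], 0.3, tolerance = 1e-12)
  # swapping conditions negates the map exactly
  cm2 <- conditionDifferenceMap(vs, 11:20, 1:10)
  expect_equal(cm2@values, -cm@values)
  # identical content in both sets gives a zero map
  Xc <- array(rep(rnorm(prod(d[1:3])), d[4]), d)
  cmz <- conditionDifferenceMap(VolumeSeries(Xc, frameRate = 10), 1:5, 6:10)
  expect_equal(max(abs(cmz@values)), 0)
  expect_error(conditionDifferenceMap(vs, integer(0), 1:3), "empty")
  expect_error(conditionDifferenceMap(vs, 1:5, 5:8), "disjoint")
})

test_that("stimulus maps pool post-minus-pre windows", {
  d <- c(3, 3, 2, 100)
  cst <- VolumeSeries(array(2, d), frameRate = 10)
  sm <- stimulusResponseMap(cst, onsetsS = c(3, 6), windowS = 1)
  expect_equal(max(abs(sm@values)), 0)
  # delta response in one voxel right after the onset
  X <- array(0, d); X[2, 2, 1, 32] <- 5
  smd <- stimulusResponseMap(VolumeSeries(X, frameRate = 10), 3, 1)
  expect_gt(smd@values[2, 2, 1], 0)
  expect_equal(sum(smd@values != 0), 1)
  # onsets too close to the edge are dropped and reported
  expect_message(stimulusResponseMap(cst, c(0.2, 5)), "dropped")
  expect_error(stimulusResponseMap(cst, 0.2), "no onset")
  # planted kernel response matches the analytic window mean
  rate <- 100
  k <- makeKernel("gcamp6f", rate)
  A <- 0.4
  tr <- numeric(1000)
  on <- 500
  taps <- A * kernelTaps(k)
  tr[on + seq_along(taps)] <- taps
  vs <- VolumeSeries(array(tr, c(1, 1, 1, 1000)), frameRate = rate)
  got <- stimulusResponseMap(vs, onsetsS = on / rate, windowS = 1)@values[1]
  # closed-form mean of the double exponential over the 1-s window,
  # normalized by its peak value
  tauD <- 0.6
  tauR <- uniroot(function(a) a * log(1 + tauD / a) - 0.15, c(1e-4, 10))$root
  tPk <- tauR * log(1 + tauD / tauR)
  pk <- (1 - exp(-tPk / tauR)) * exp(-tPk / tauD)
  intH <- function(t) tauD * (1 - exp(-t / tauD)) -
    1 / (1 / tauR + 1 / tauD) * (1 - exp(-t * (1 / tauR + 1 / tauD)))
  analytic <- A * intH(1) / pk / 1
  expect_lt(abs(got - analytic) / analytic, 0.02)
})

test_that("responsive-component counts normalize per region", {
  atl <- tinyAtlas(c(16, 12, 8), 3, seed = 6)
  labs <- atlasLabels(atl)
  regs <- unname(regionLabels(atl))
  reg <- c(rep(regs[1], 4), rep(regs[2], 2), rep(regs[3], 2))
  set.seed(7)
  drive <- as.numeric(stats::filter(rnorm(300), rep(1 / 8, 8),
                                    circular = TRUE))
  tra <- sapply(1:8, function(i)
    if (i <= 6) drive + rnorm(300, sd = 0.5) else rnorm(300))
  cs <- new("ComponentSet", maps = array(0.1, c(dim(labs), 8)),
            traces = tra, traceScale = rep(1, 8), signFixed = TRUE,
            regionLabel = reg, artifact = rep("activity", 8),
            nRegionsPresent = rep(NA_integer_, 8),
            nObjects = rep(NA_integer_, 8), meta = list())
  counts <- countResponsive(cs, drive, rMin = 0.1, atlas = atl)
  expect_equal(unname(counts[regs]), c(1, 0.5, 0))
  # a lone responsive component gives 1 in its region, 0 elsewhere
  cs1 <- cs
  cs1@traces <- cbind(drive, tra[, 7:8] * 0 + rnorm(300))[, c(1, 2, 2)]
  cs1@regionLabel <- c(regs[1], regs[2], regs[3])
  cs1@traces <- cs1@traces[, 1:3]
  cs1@maps <- cs@maps[, , , 1:3]
  cs1@artifact <- rep("activity", 3)
  cs1@traceScale <- rep(1, 3)
  cs1@nRegionsPresent <- rep(NA_integer_, 3)
  cs1@nObjects <- rep(NA_integer_, 3)
  c1 <- countResponsive(cs1, drive, atlas = atl)
  expect_equal(unname(c1[regs]), c(1, 0, 0))
  expect_warning(countResponsive(cs1, -drive, atlas = atl), "no responsive")
})

test_that("two-color rendering respects the sign-to-channel convention", {
  d <- c(6, 5, 3)
  bg <- array(runif(prod(d)), d)
  pos <- array(abs(rnorm(prod(d))), d)
  cmPos <- new("ConditionMap", values = pos, conditionA = "walk",
               conditionB = "rest",
               colorConvention = c(positive = "green", negative = "magenta"))
  sl <- exportTwocolor(cmPos, bg)
  bgn <- (bg - min(bg)) / (max(bg) - min(bg))
  for (z in seq_len(d[3])) {
    rgb <- sl[[z]]
    # all-positive map: no magenta overlay anywhere (red == blue == bg part)
    expect_equal(rgb[, , 1], rgb[, , 3])
    expect_equal(rgb[, , 1], pmin(0.5 * bgn[, , z], 1))
  }
  # negated map: channel roles exactly swapped
  cmNeg <- new("ConditionMap", values = -pos, conditionA = "walk",
               conditionB = "rest",
               colorConvention = c(positive = "green", negative = "magenta"))
  sn <- exportTwocolor(cmNeg, bg)
  for (z in seq_len(d[3])) {
    expect_equal(sn[[z]][, , 1], sl[[z]][, , 2])   # magenta gets old green
    expect_equal(sn[[z]][, , 2], sl[[z]][, , 1])
  }
  # single positive voxel: exactly one colored pixel in its slice
  one <- array(0, d); one[3, 2, 2] <- 1
  cm1 <- new("ConditionMap", values = one, conditionA = "a",
             conditionB = "b",
             colorConvention = c(positive = "green", negative = "magenta"))
  s1 <- exportTwocolor(cm1, array(0, d))
  colored <- s1[[2]][, , 2] - s1[[2]][, , 1]
  expect_equal(sum(colored != 0), 1)
  expect_gt(colored[3, 2], 0)
  for (z in c(1, 3)) expect_equal(max(abs(s1[[z]])), 0)
  expect_warning(
    exportTwocolor(new("ConditionMap", values = array(0, d),
                       conditionA = "a", conditionB = "b",
                       colorConvention = c(positive = "green",
                                           negative = "magenta")), bg),
    "all-zero")
})

test_that("permutation sign test localizes a planted condition effect", {
  # walk-coupled source: significant exactly on its support when noise-free
  atl <- tinyAtlas(c(16, 12, 8), 3, seed = 8)
  tr <- makeGroundTruth(atl, 2, durationS = 30, frameRateHz = 20, seed = 9,
                        coupling = c("walk", "silent"), bleachLossPer30s = 0,
                        amplitude = 20)
  mv <- renderMovie(tr, baseline = 100, noise = list(gaussianSd = 0),
                    seed = 10)
  st <- behaviorState(tr@behavior)
  p <- mapPermutationTest(mv, which(st == "walk"), which(st == "rest"),
                          nPerm = 199, seed = 11)
  cm <- conditionDifferenceMap(mv, which(st == "walk"), which(st == "rest"))
  supp <- tr@sourceMaps[, , , 1] > 0
  expect_true(all(p[supp] < 0.01))
  expect_true(all(cm@values[supp] > 0))
  expect_true(all(p[!supp] >= 0.01))
})
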