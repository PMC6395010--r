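# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops / closed forms, independent of the implementation paths
# they check.

# fold a 4D (x,y,z,t) array into voxels x frames
flat4 <- function(a) {
  d <- dim(a)
  dim(a) <- c(prod(d[1:3]), d[4])
  a
}

# small standard phantom used across files
tinyAtlas <- function(shape = c(24, 16, 8), nRegions = 3, seed = 1)
  makeAtlas(shape, nRegions, seed = seed)

# direct O(n*k) causal convolution (double loop)
convOracle <- function(x, taps) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_along(taps)) {
      if (t - k + 1 >= 1) out[t] <- out[t] + taps[k] * x[t - k + 1]
    }
  }
  out
}

# exhaustive-scan shoulder oracle: first index whose centered slope of the
# [0,1]-normalized log spectrum crosses -1
shoulderOracle <- function(sv) {
  n <- length(sv)
  x <- (0:(n - 1)) / (n - 1)
  y <- log(sv)
  if (max(y) == min(y)) return(NA_integer_)
  y <- (y - min(y)) / (max(y) - min(y))
  s <- vapply(2:(n - 1), function(i) (y[i + 1] - y[i - 1]) /
                (x[i + 1] - x[i - 1]), numeric(1))
  idx <- 2:(n - 1)
  if (s[1] == -1) return(idx[1])
  for (j in 2:length(s)) {
    if (s[j] == -1 || (s[j - 1] + 1) * (s[j] + 1) < 0) return(idx[j])
  }
  NA_integer_
}

# random decaying singular spectrum with a signal head and a noise tail
randomSpectrum <- function() {
  k <- sample(5:30, 1)
  sort(exp(-c(stats::runif(k, 0, 3),
              3 + cumsum(stats::runif(170, 0, 0.02)))), decreasing = TRUE)
}

# piecewise log-linear spectrum: normalized slopes -0.2 then -3 with the
# continuous join at 5/7 of the index range; on a 28-point grid the -1
# crossing of the centered slope falls exactly at index 20
piecewiseSpectrum <- function(n = 28, joinFrac = 5 / 7) {
  x <- (0:(n - 1)) / (n - 1)
  y <- ifelse(x <= joinFrac, 1 - 0.2 * x,
              1 - 0.2 * joinFrac - 3 * (x - joinFrac))
  exp(y)
}

# brute-force minimum-cost assignment by permutation enumeration
assignOracle <- function(cost) {
  nr <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    cc <- sum(cost[cbind(seq_len(nr), p[seq_len(nr)])])
    if (cc < bestCost) { bestCost <- cc; best <- p[seq_len(nr)] }
  }
  list(assignment = best, cost = bestCost)
}

# a hand-made GroundTruth with full control over maps/traces/motion/bleach
manualTruth <- function(maps, traces, motionPath = NULL, bleach = NULL,
                        frameRate = 10, probe = "gcamp6f") {
  nt <- nrow(traces)
  if (is.null(motionPath)) motionPath <- matrix(0, nt, 3)
  if (is.null(bleach)) bleach <- rep(1, nt)
  beh <- new("BehaviorTrace", frameRate = frameRate,
             state = factor(rep("rest", nt),
                            levels = c("rest", "walk", "groom")),
             flowLeft = numeric(nt), flowRight = numeric(nt))
  new("GroundTruth", sourceMaps = maps, sourceTraces = traces,
      sourceRegion = rep(1L, dim(maps)[4]), motionPath = motionPath,
      bleachCurve = bleach, behavior = beh,
      stimuli = makeStimuli(nt / frameRate + 10), frameRate = frameRate,
      probe = probe, coupling = rep("manual", dim(maps)[4]),
      seed = 0L)
}
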