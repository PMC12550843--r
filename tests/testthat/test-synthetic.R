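test_that("generator is reproducible and validates its configuration", {
  cfg <- boundPreset()
  a <- simulateTrajectory(cfg, nFrames = 500, seed = 5)
  b <- simulateTrajectory(cfg, nFrames = 500, seed = 5)
  expect_identical(a@colvar@values, b@colvar@values)
  expect_identical(a@conformerState, b@conformerState)
  c_ <- simulateTrajectory(cfg, nFrames = 500, seed = 6)
  expect_false(identical(a@colvar@values, c_@colvar@values))
  # invalid transition matrix rejected
  bad <- cfg
  bad@transition <- matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_error(simulateTrajectory(bad), "sum to 1")
  bad2 <- cfg
  bad2@coupling <- 1.5
  expect_error(simulateTrajectory(bad2), "coupling")
})

test_that("presets are valid and expose the documented structure", {
  sol <- solutionPreset()
  expect_true(validObject(sol))
  expect_equal(sol@coupling, 0)
  expect_length(sol@puckerStates, 1L)
  bnd <- boundPreset()
  expect_true(validObject(bnd))
  expect_equal(bnd@coupling, 0.9)
  expect_equal(vapply(bnd@puckerStates, `[[`, "", "name"),
               c("chair", "halfchair"))
  expect_equal(bnd@pairing, c("chair", "halfchair"))
  expect_length(sol@dihedrals, 5L)
})

test_that("full coupling pins the pucker state to the conformer partner", {
  tr <- simulateTrajectory(boundPreset(coupling = 1), nFrames = 2000,
                           seed = 7)
  partner <- c(s1 = "chair", s2 = "halfchair")
  expect_equal(tr@puckerState, unname(partner[tr@conformerState]))
})

test_that("zero coupling decorrelates conformer and pucker labels", {
  tr <- simulateTrajectory(boundPreset(coupling = 0), nFrames = 10000,
                           seed = 8)
  # empirical mutual information against a permutation-null bound
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    sum(tab * log(tab / outer(pa, pb)), na.rm = TRUE)
  }
  obs <- mi(tr@conformerState, tr@puckerState)
  set.seed(88)
  null <- replicate(200, mi(tr@conformerState, sample(tr@puckerState)))
  expect_lt(obs, max(null) * 3 + 1e-4)
})

test_that("state frequencies converge to the stationary distribution", {
  cfg <- boundPreset()
  statio <- stationaryDistribution(cfg@transition)
  expect_equal(statio, c(0.6, 0.4), tolerance = 1e-12)
  tr <- simulateTrajectory(cfg, nFrames = 100000, seed = 9)
  freq <- as.numeric(table(factor(tr@conformerState,
                                  c("s1", "s2")))) / 100000
  # 3 sigma with the chain's ~40-frame correlation time folded in
  se <- sqrt(statio * (1 - statio) / (1e5 / 40))
  expect_lt(max(abs(freq - statio)), 3 * max(se))
})

test_that("generated dihedral marginals match the configured circular means", {
  cfg <- boundPreset()
  tr <- simulateTrajectory(cfg, nFrames = 20000, seed = 10)
  circMean <- function(x) atan2(mean(sin(x)), mean(cos(x)))
  for (s in seq_along(cfg@states)) {
    st <- cfg@states[[s]]
    idx <- tr@conformerState == st$name
    for (d in cfg@dihedrals) {
      m <- circMean(tr@colvar@values[idx, d])
      se <- (1 / sqrt(st$kappa)) / sqrt(sum(idx))
      expect_lt(abs(wrapAngle(m - st$mean[[d]])), 3 * se + 1e-3)
    }
  }
})

test_that("emitted ring geometries reproduce the frame pucker coordinates", {
  tr <- simulateTrajectory(boundPreset(), nFrames = 100, seed = 11)
  rings <- emitRings(tr)
  pc <- cremerPople(rings)
  expect_lt(max(abs(pc@Q - tr@config@Q)), 1e-8)
  expect_lt(max(abs(pc@theta - tr@colvar@values[, "theta"])), 1e-8)
  dphi <- abs(wrapAngle(pc@phi - tr@colvar@values[, "phi"]))
  expect_lt(max(dphi), 1e-8)
})

test_that("pipeline recovers the designed coupling sign and monotone strength", {
  rBoth <- function(c_, seed) {
    tr <- simulateTrajectory(boundPreset(coupling = c_), nFrames = 5000,
                             seed = seed)
    oh <- cbind(s1 = as.numeric(tr@conformerState == "s1"),
                s2 = as.numeric(tr@conformerState == "s2"))
    r <- correlatePhase(oh, theta = tr@colvar@values[, "theta"])@r
    c(r["s1", "theta"], r["s2", "theta"])
  }
  cs <- c(0.5, 0.75, 1.0)
  out <- sapply(seq_along(cs), function(i) rBoth(cs[i], 100 + i))
  # opposite signs for every coupling level
  expect_true(all(out[1, ] < 0 & out[2, ] > 0))
  # |r| monotone in the coupling
  expect_true(all(diff(abs(out[1, ])) > 0))
  expect_true(all(diff(abs(out[2, ])) > 0))
})

test_that("hidden labels serialize alongside the COLVAR table", {
  tr <- simulateTrajectory(boundPreset(), nFrames = 50, seed = 13)
  f <- tempfile()
  writeHiddenLabels(tr, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 50L)
  expect_equal(back$conformerState, tr@conformerState)
  f2 <- tempfile()
  writeColvar(tr@colvar, f2)
  round <- readColvar(f2)
  expect_equal(round@values, tr@colvar@values)
})
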