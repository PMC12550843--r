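test_that("letter intervals partition (-pi, pi] with the audited boundary ownership", {
  set.seed(2)
  ang <- runif(1e4, -pi, pi)
  ang[ang == -pi] <- pi
  lp <- letterForAngle(ang)
  lo <- letterForAngle(ang, "omega")
  expect_false(anyNA(lp))
  expect_false(anyNA(lo))
  expect_setequal(unique(lp), c("C", "G+", "A+", "T", "A-", "G-"))
  expect_setequal(unique(lo), c("gg", "gt", "tg"))

  eps <- 1e-9
  # phi/psi boundaries: closed at the lower bound; T owns +/-2.62
  expect_equal(letterForAngle(c(0.52 - eps, 0.52)), c("C", "G+"))
  expect_equal(letterForAngle(c(1.57 - eps, 1.57)), c("G+", "A+"))
  expect_equal(letterForAngle(c(2.62 - eps, 2.62)), c("A+", "T"))
  expect_equal(letterForAngle(c(-0.52, -0.52 - eps)), c("C", "G-"))
  expect_equal(letterForAngle(c(-1.57, -1.57 - eps)), c("G-", "A-"))
  expect_equal(letterForAngle(c(-2.62 + eps, -2.62)), c("A-", "T"))
  expect_equal(letterForAngle(pi), "T")
  # omega boundaries: 0 is owned by gt, +/-2.62 by tg
  expect_equal(letterForAngle(c(-eps, 0), "omega"), c("gg", "gt"))
  expect_equal(letterForAngle(c(2.62 - eps, 2.62), "omega"), c("gt", "tg"))
  expect_equal(letterForAngle(c(-2.62 + eps, -2.62), "omega"), c("gg", "tg"))
  expect_equal(letterForAngle(pi, "omega"), "tg")
})

test_that("two-well profiles split into basins and angles inherit the basin letter", {
  tw <- twoWellProfile()
  b <- findBasins(tw$g)
  expect_length(b$minima, 2L)
  expect_equal(sort(b$letters), c("C", "T"))
  expect_lt(abs(wrapAngle(sort(b$minima)[1] - 0.3)), 0.1)
  expect_lt(abs(wrapAngle(sort(b$minima)[2] - 3.0)), 0.1)
  bnd <- sort(b$boundaries)
  expect_lt(abs(bnd[1] - (-1.4)), 0.1)
  expect_lt(abs(bnd[2] - 1.6), 0.1)
  # the defining behaviour: 0.6 rad is in the raw G+ interval but inside
  # the basin of the minimum at 0.3, so it inherits C
  expect_equal(letterForAngle(0.6), "G+")
  expect_equal(basinLetter(0.6, b), "C")
  # deep in the other basin
  expect_equal(basinLetter(2.5, b), "T")
})

test_that("flat and single-well profiles give one circle-covering basin", {
  flat <- rep(1, 72)
  b <- findBasins(flat)
  expect_length(b$minima, 1L)
  expect_length(b$boundaries, 0L)
  centers <- seq(-pi, pi, length.out = 73)[-1] - pi / 72
  onewell <- 3 * (1 - cos(centers))
  b1 <- findBasins(onewell)
  expect_length(b1$minima, 1L)
  expect_equal(b1$letters, "C")
  expect_equal(basinLetter(c(-3, -1, 0, 1, 3), b1), rep("C", 5))
})

test_that("a minimum at an interval boundary takes the half-open owner's letter", {
  # single well centred exactly at 0.52: the bin centres never hit 0.52
  # exactly, so pin the basin by evaluating the letter directly
  expect_equal(letterForAngle(0.52), "G+")
  centers <- seq(-pi, pi, length.out = 73)[-1] - pi / 72
  g <- 3 * (1 - cos(centers - 0.52))
  b <- findBasins(g)
  # minimum lands on the bin centre nearest 0.52; its letter is the
  # letter of that centre under the half-open partition
  expect_equal(b$letters, letterForAngle(b$minima))
})

test_that("basin detection needs at least two populated bins", {
  expect_error(findBasins(c(1, NA, NA)), "2 populated bins")
})

test_that("conformer strings follow reducing-end traversal with branch separators", {
  # unbranched 2-linkage glycan under identity basins: pure letter lookup
  topo <- glycanTopology(data.frame(
    name = c("l1", "l2"), from = c("r1", "r2"), to = c("r2", "r3"),
    carbon = c(4L, 4L), hasOmega = c(FALSE, FALSE)))
  vals <- cbind("l1.phi" = 0.0, "l1.psi" = 3.0,
                "l2.phi" = -1.0, "l2.psi" = 2.0)
  tab <- colvarTable(time = 0, values = vals)
  basins <- identityBasins(colnames(vals))
  ser <- assignConformers(tab, basins, topo)
  expect_equal(conformerStrings(ser), "C T G- A+")

  # branched: 1-6 and 1-3 arms from one residue; separator "6-" precedes
  # the higher-carbon arm, which is traversed first
  topo2 <- presetTopology()
  vals2 <- cbind("arm6.phi" = 0.0, "arm6.psi" = 3.0, "arm6.omega" = 1.0,
                 "arm3.phi" = -1.0, "arm3.psi" = 2.0)
  tab2 <- colvarTable(time = 0, values = vals2)
  ser2 <- assignConformers(tab2, identityBasins(colnames(vals2)), topo2)
  expect_equal(conformerStrings(ser2), "6- C T gt 3- G- A+")

  # frames with a missing angle are labelled NA
  vals3 <- rbind(vals2, vals2)
  vals3[2, 1] <- NA
  tab3 <- colvarTable(time = 0:1, values = vals3)
  ser3 <- assignConformers(tab3, identityBasins(colnames(vals2)), topo2)
  expect_true(is.na(conformerStrings(ser3)[2]))
  expect_false(is.na(conformerStrings(ser3)[1]))
})

test_that("nested junctions traverse higher-carbon branches first", {
  # core -> (1-6 arm -> nested (1-4, 1-3)), plus core 1-2 arm
  topo <- glycanTopology(data.frame(
    name = c("a6", "a2", "n4", "n3"),
    from = c("core", "core", "man6", "man6"),
    to = c("man6", "man2", "x4", "x3"),
    carbon = c(6L, 2L, 4L, 3L),
    hasOmega = c(TRUE, FALSE, FALSE, FALSE)))
  cols <- c("a6.phi", "a6.psi", "a6.omega", "n4.phi", "n4.psi",
            "n3.phi", "n3.psi", "a2.phi", "a2.psi")
  vals <- matrix(0, 1, length(cols), dimnames = list(NULL, cols))
  tab <- colvarTable(time = 0, values = vals)
  ser <- assignConformers(tab, identityBasins(cols), topo)
  expect_equal(conformerStrings(ser),
               "6- C C gt 4- C C 3- C C 2- C C")
})

test_that("distributions rank by probability with lexicographic tie-break and 5% folding", {
  s <- c(rep("A A", 3), "B B")
  d <- conformerDistribution(s, minProb = 0)
  tabd <- asDataFrame(d)
  expect_equal(tabd$probability, c(0.75, 0.25))
  expect_equal(tabd$shortLabel, c("#1", "#2"))
  expect_equal(tabd$string[1], "A A")
  # 50/50 tie: lexicographically smaller string is #1
  d2 <- asDataFrame(conformerDistribution(c("Z", "A"), minProb = 0))
  expect_equal(d2$string[d2$shortLabel == "#1"], "A")
  # a 4%-populated conformer folds into "other" at the 5% threshold
  s3 <- c(rep("A", 96), rep("B", 4))
  d3 <- asDataFrame(conformerDistribution(s3, minProb = 0.05))
  expect_equal(d3$shortLabel[d3$string == "B"], "other")
  expect_equal(sum(d3$probability), 1)
  # all frames identical -> single conformer with probability 1
  d4 <- asDataFrame(conformerDistribution(rep("X", 10)))
  expect_equal(d4$probability, 1)
})

test_that("basin inheritance never increases the conformer count", {
  set.seed(9)
  tr <- simulateTrajectory(boundPreset(), nFrames = 4000, seed = 9)
  topo <- presetTopology()
  bm <- basinMap(tr@colvar)
  inherited <- assignConformers(tr@colvar, bm, topo)
  raw <- assignConformers(tr@colvar,
                          identityBasins(names(bm@entries)), topo)
  expect_lte(length(unique(stats::na.omit(conformerStrings(inherited)))),
             length(unique(stats::na.omit(conformerStrings(raw)))))
})

test_that("classification is deterministic for identical input", {
  tr <- simulateTrajectory(boundPreset(), nFrames = 2000, seed = 4)
  topo <- presetTopology()
  run <- function() {
    bm <- basinMap(tr@colvar)
    conformerStrings(assignConformers(tr@colvar, bm, topo))
  }
  expect_identical(run(), run())
})

test_that("moving-average populations converge to the Markov stationary distribution", {
  cfg <- boundPreset()
  tr <- simulateTrajectory(cfg, nFrames = 20000, seed = 12)
  bm <- basinMap(tr@colvar)
  ser <- assignConformers(tr@colvar, bm, presetTopology())
  # the moving average of a window of w frames of a chain with ~40-frame
  # correlation time fluctuates with sd ~ sqrt(p q tau / w); the drift
  # tolerance has to sit above that band
  pt <- populationTimeseries(ser, window = 5000, nTop = 2, tol = 0.15)
  expect_true(all(pt$converged))
  # final moving average close to the analytic stationary probabilities
  statio <- sort(stationaryDistribution(cfg@transition), decreasing = TRUE)
  finals <- sort(pt$average[nrow(pt$average), ], decreasing = TRUE)
  # binomial-ish 3 sigma at window 2000, inflated for chain correlation
  expect_lt(max(abs(finals - statio)), 0.1)
  # window = 1 returns the raw indicator
  pt1 <- populationTimeseries(ser, window = 1, nTop = 1)
  expect_setequal(unique(pt1$average[, 1]), c(0, 1))
  # constant series -> flat line at 1
  ptc <- populationTimeseries(rep("K", 50), window = 5, nTop = 1)
  expect_true(all(ptc$average == 1))
  expect_error(populationTimeseries(rep("K", 5), window = 10), "exceeds")
})
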