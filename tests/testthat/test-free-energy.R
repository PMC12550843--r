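test_that("probability-to-free-energy conversion follows -kB*T*ln(P)", {
  expect_equal(probabilityToFE(1, 310.15), 0)
  expect_equal(probabilityToFE(1, 77), 0)
  # derived oracle: P = 0.8 vs 0.2 differ by kB*T*ln(4)
  dd <- probabilityToFE(0.2, 310.15) - probabilityToFE(0.8, 310.15)
  expect_equal(dd, 0.0083144626 * 310.15 * log(4), tolerance = 1e-12)
  expect_equal(dd, 3.575, tolerance = 2e-3)
  expect_true(is.na(probabilityToFE(0)))
  expect_error(probabilityToFE(1.2), "0, 1")
  expect_error(probabilityToFE(-0.1), "0, 1")
})

test_that("block statistics reproduce the printed formula chain", {
  x <- c(1.0, 2.0, 4.0, 3.0, 5.0)
  st <- blockStats(x)
  n <- 5
  vref <- (n / (n - 1)) * (mean(x^2) - mean(x)^2)
  expect_equal(st$var, vref)
  expect_equal(st$sem, sqrt(vref / n))
  expect_equal(st$mean, mean(x))
  # the N/(N-1) corrected variance equals the sample variance
  expect_equal(st$var, var(x))
  # permutation invariance
  st2 <- blockStats(x[c(3, 5, 1, 4, 2)])
  expect_equal(st2$sem, st$sem)
  # NA blocks are dropped and counted out
  st3 <- blockStats(c(x, NA))
  expect_equal(st3$n, 5L)
  expect_equal(st3$sem, st$sem)
  expect_true(is.na(blockStats(c(2, NA))$sem))
})

test_that("block SEM follows the sigma/sqrt(n) law on iid normals", {
  set.seed(21)
  x <- rnorm(1e5)
  blocks <- vapply(split(x, rep(1:10, each = 1e4)), mean, 1)
  st <- blockStats(blocks)
  expect_lt(abs(st$sem - 1 / sqrt(1e5)) / (1 / sqrt(1e5)), 0.2)
})

test_that("two-state profile recovers the analytic free-energy gap", {
  set.seed(22)
  x <- ifelse(runif(1e5) < 0.8, 0.25, 0.75)
  prof <- feProfile1D(x, bins = 2, nBlocks = 10, range = c(0, 1))
  g <- deltaG(prof)
  expect_equal(min(g), 0)
  dd <- abs(diff(g))
  ref <- kBoltzmann * 310.15 * log(4)
  sem <- sqrt(sum(standardError(prof)^2))
  expect_lt(abs(dd - ref), 3 * sem)
  # a constant series occupies a single bin at deltaG = 0 with zero SEM
  pc <- feProfile1D(rep(0.5, 100), bins = 4, nBlocks = 2, range = c(0, 1))
  expect_equal(sum(!is.na(deltaG(pc))), 1L)
  expect_equal(deltaG(pc)[!is.na(deltaG(pc))], 0)
  expect_equal(standardError(pc)[!is.na(deltaG(pc))], 0)
  expect_error(feProfile1D(x, nBlocks = 1), "nBlocks")
})

test_that("Boltzmann inversion recovers a double-well potential within block errors", {
  # prescribed potential (kJ/mol) and inverse-CDF sampling, both
  # independent of the free-energy module
  set.seed(23)
  U <- function(x) 6 * (1 - cos(2 * x)) + 1.5 * sin(x)
  kT <- kBoltzmann * 310.15
  grid <- seq(-pi, pi, length.out = 20001)
  dens <- exp(-U(grid) / kT)
  cdf <- cumsum(dens) / sum(dens)
  x <- grid[findInterval(runif(1e5), cdf) + 1]
  prof <- feProfile1D(x, bins = 72, nBlocks = 10, periodic = TRUE)
  g <- deltaG(prof)
  sem <- standardError(prof)
  pop <- !is.na(g) & prof@counts > 50 & !is.na(sem)
  uref <- U(prof@centers)
  # align additive constants by occupancy-weighted offset
  off <- sum((uref - g)[pop] * prof@counts[pop]) / sum(prof@counts[pop])
  cover <- abs(g[pop] + off - uref[pop]) < 3 * sem[pop]
  expect_gte(mean(cover), 0.95)
})

test_that("2D surfaces mask empties, stay flat for uniform input and wrap the phi seam", {
  set.seed(24)
  n <- 2e5
  s <- feSurface2D(runif(n), runif(n), bins = c(10, 10),
                   xrange = c(0, 1), yrange = c(0, 1))
  g <- deltaG(s)
  expect_equal(min(g, na.rm = TRUE), 0)
  # multinomial fluctuation bound: sd(dG) ~ kT/sqrt(n p) per cell
  kT <- kBoltzmann * 310.15
  expfluct <- kT / sqrt(n / 100)
  expect_lt(max(g, na.rm = TRUE) - min(g, na.rm = TRUE), 6 * expfluct)
  # all mass in one cell: deltaG = 0 there, everything else masked
  s1 <- feSurface2D(rep(0.5, 100), rep(0.5, 100), bins = c(5, 5),
                    xrange = c(0, 1), yrange = c(0, 1))
  expect_equal(sum(!is.na(deltaG(s1))), 1L)
  expect_equal(deltaG(s1)[3, 3], 0)
  expect_error(feSurface2D(numeric(0), numeric(0), bins = c(5, 5),
                           xrange = 0:1, yrange = 0:1), "populated")
  # samples on the phi seam stay one contiguous basin after wrapping
  phiSeam <- wrapAngle(rnorm(5000, pi, 0.05))
  other <- rnorm(5000, 0, 0.3)
  ss <- feSurface2D(phiSeam, other, bins = c(36, 12), periodicX = TRUE,
                    yrange = c(-2, 2))
  gg <- deltaG(ss)
  occ <- rowSums(!is.na(gg)) > 0
  # occupied x-bins are the first and last few (the two sides of the seam)
  expect_true(occ[1] && occ[36])
  expect_false(any(occ[10:27]))
})

test_that("profile and surface tables round-trip their numeric content", {
  set.seed(25)
  prof <- feProfile1D(rnorm(5000), bins = 20, nBlocks = 5)
  f <- tempfile()
  writeProfile(prof, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$deltaG, deltaG(prof), tolerance = 1e-9)
  surf <- feSurface2D(rnorm(5000), rnorm(5000), bins = c(8, 8))
  f2 <- tempfile()
  writeSurface(surf, f2)
  expect_true(file.exists(f2))
  expect_equal(length(readLines(f2)), 2 + 8)
})
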