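test_that("featurization maps angles onto the unit circle", {
  vals <- cbind("l.phi" = c(0, pi, pi / 2), "l.psi" = c(0.3, -0.3, 2))
  tab <- colvarTable(0:2, vals)
  X <- featurize(tab)
  expect_equal(colnames(X), c("l.phi.sin", "l.phi.cos",
                              "l.psi.sin", "l.psi.cos"))
  expect_equal(unname(X[1, 1:2]), c(0, 1))
  expect_equal(unname(X[2, 1:2]), c(sin(pi), -1))
  expect_equal(unname(X[3, 1:2]), c(1, cos(pi / 2)))
  expect_equal(rowSums(X[, 1:2]^2), rep(1, 3))
  # missing frames dropped with a message
  vals[2, 1] <- NA
  tab2 <- colvarTable(0:2, vals)
  expect_message(X2 <- featurize(tab2), "dropped")
  expect_equal(nrow(X2), 2L)
  expect_equal(attr(X2, "frames"), c(1L, 3L))
  expect_error(featurize(tab, dihedrals = "nope"), "nope")
  expect_error(featurize(colvarTable(0, cbind(theta = 1))), "no dihedral")
})

test_that("latent space: orthonormal loadings, exact reconstruction, sign convention", {
  set.seed(31)
  tr <- simulateTrajectory(boundPreset(), nFrames = 3000, seed = 31)
  X <- featurize(tr@colvar, tag = "bound")
  sp <- fitLatent(X)
  L <- featureLoadings(sp)
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centred features
  Xc <- sweep(X, 2, sp@center)
  expect_equal(scores(sp) %*% t(L), Xc, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_false(is.unsorted(-explainedVariance(sp)))
  expect_equal(sum(explainedVariance(sp)), 1)
  # sign fixed: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(L)))
    expect_gt(L[which.max(abs(L[, j])), j], 0)
})

test_that("concatenation is idempotent and degenerate data load onto PC1", {
  set.seed(32)
  tr <- simulateTrajectory(boundPreset(), nFrames = 1000, seed = 32)
  X <- featurize(tr@colvar, tag = "a")
  one <- fitLatent(X)
  two <- fitLatent(list(X, X))
  expect_equal(featureLoadings(two), featureLoadings(one),
               tolerance = 1e-8)
  expect_equal(nrow(scores(two)), 2 * nrow(scores(one)))
  # data on a line in feature space: PC1 explains ~100%
  t_ <- seq(-1, 1, length.out = 200)
  lineX <- outer(t_, c(1, 2, -1)) + 5
  colnames(lineX) <- c("a", "b", "c")
  lin <- fitLatent(lineX)
  expect_gt(explainedVariance(lin)[1], 1 - 1e-12)
  # mismatched columns refused with the offender named
  Y <- X
  colnames(Y)[1] <- "other.sin"
  expect_error(fitLatent(list(X, Y)), "other.sin")
})

test_that("two-conformer data separate in the latent space", {
  tr <- simulateTrajectory(boundPreset(), nFrames = 4000, seed = 33)
  X <- featurize(tr@colvar)
  sp <- fitLatent(X)
  s <- scores(sp)[, 1:2, drop = FALSE]
  lab <- tr@conformerState[attr(X, "frames")]
  m1 <- colMeans(s[lab == "s1", , drop = FALSE])
  m2 <- colMeans(s[lab == "s2", , drop = FALSE])
  spread <- sqrt(mean(c(apply(s[lab == "s1", ], 2, var),
                        apply(s[lab == "s2", ], 2, var))))
  # cluster centres separated by many within-cluster widths
  expect_gt(sqrt(sum((m1 - m2)^2)), 3 * spread)
  # latent FES on the tagged subset
  fes <- latentFES(sp, temperature = 310.15)
  expect_s4_class(fes, "FreeEnergySurface")
  expect_equal(dim(deltaG(fes)), c(35L, 35L))
  expect_error(latentFES(sp, tag = "nope"), "unknown dataset tag")
})

test_that("one-hot encoding is binary with zero rows outside the set", {
  oh <- oneHot(c("a", "b", "a"), include = c("a", "b"))
  expect_equal(unname(oh), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_message(oh2 <- oneHot(c("a", "z"), include = c("a", "b")),
                 "outside")
  expect_equal(unname(oh2[2, ]), c(0, 0))
  expect_true(all(rowSums(oh2) %in% c(0, 1)))
  expect_error(oneHot(c("a"), include = character(0)), "empty")
  # missing labels propagate as NA rows
  oh3 <- oneHot(c("a", NA), include = c("a"))
  expect_true(is.na(oh3[2, 1]))
})

test_that("Pearson matrices: unit diagonal, symmetry, NA for constants", {
  set.seed(34)
  x <- rnorm(100)
  y <- 2 * x + rnorm(100, 0, 0.01)
  cm <- correlatePhase(cbind(a = x, b = y), theta = rnorm(100))
  r <- cm@r
  expect_equal(diag(r), c(a = 1, b = 1, theta = 1))
  expect_equal(r, t(r))
  expect_gt(r["a", "b"], 0.99)
  expect_warning(cc <- correlatePhase(cbind(k = rep(1, 50)),
                                      v = rnorm(50)),
                 "constant")
  expect_true(is.na(cc@r["k", "v"]))
  expect_error(correlatePhase(cbind(a = 1:5), b = 1:4), "row counts")
  expect_error(correlatePhase(cbind(a = 1:2), b = 1:2), "at least 3")
})

test_that("Pearson r is affine-invariant and antisymmetric under negation", {
  set.seed(35)
  x <- rnorm(200); y <- x + rnorm(200)
  r0 <- correlatePhase(a = x, b = y)@r["a", "b"]
  r1 <- correlatePhase(a = 3 * x + 7, b = 0.5 * y - 2)@r["a", "b"]
  expect_equal(r1, r0, tolerance = 1e-12)
  r2 <- correlatePhase(a = -x, b = y)@r["a", "b"]
  expect_equal(r2, -r0, tolerance = 1e-12)
})

test_that("conformer-theta coupling is recovered with the designed sign", {
  # strong coupling: point-biserial r large and opposite for the two
  # states; zero coupling: |r| within the null sampling band
  tr <- simulateTrajectory(boundPreset(coupling = 1), nFrames = 10000,
                           seed = 36)
  oh <- cbind(s1 = as.numeric(tr@conformerState == "s1"),
              s2 = as.numeric(tr@conformerState == "s2"))
  th <- tr@colvar@values[, "theta"]
  cm <- correlatePhase(oh, theta = th)@r
  expect_gt(cm["s2", "theta"], 0.8)
  expect_lt(cm["s1", "theta"], -0.8)
  tr0 <- simulateTrajectory(boundPreset(coupling = 0), nFrames = 10000,
                            seed = 37)
  oh0 <- cbind(s1 = as.numeric(tr0@conformerState == "s1"),
               s2 = as.numeric(tr0@conformerState == "s2"))
  cm0 <- correlatePhase(oh0, theta = tr0@colvar@values[, "theta"])@r
  # theta draws are frame-independent at c = 0, so the plain
  # 3/sqrt(n) null band applies
  expect_lt(max(abs(cm0[c("s1", "s2"), "theta"])), 3 / sqrt(10000))
})
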