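# fixtures built in code, shared across test files

# random ring pucker parameters away from the poles
randomPucker <- function(n, thetaRange = c(5, 175)) {
  data.frame(Q = runif(n, 0.2, 0.8),
             theta = runif(n, thetaRange[1], thetaRange[2]) * pi / 180,
             phi = runif(n, 0, 2 * pi))
}

# brute-force signed dihedral, written independently of dihedralAngle():
# rotate into a frame where b2 is the z axis and read the polar angle of
# the projected bond vectors
bruteDihedral <- function(a, b, c, d) {
  b2 <- c - b
  ez <- b2 / sqrt(sum(b2^2))
  v1 <- (a - b) - sum((a - b) * ez) * ez
  v2 <- (d - c) - sum((d - c) * ez) * ez
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  sgn <- sign(sum(ez * c(v1[2] * v2[3] - v1[3] * v2[2],
                         v1[3] * v2[1] - v1[1] * v2[3],
                         v1[1] * v2[2] - v1[2] * v2[1])))
  ang <- acos(pmin(pmax(cosang, -1), 1))
  # IUPAC sign: positive when d rotates clockwise viewed along b -> c
  if (sgn == 0) ang else sgn * ang
}

# two-well periodic free-energy profile with minima pinned at 0.3 and
# 3.0 rad and maxima at the arc boundaries 1.6 and -1.4 rad
twoWellProfile <- function(bins = 72) {
  centers <- seq(-pi, pi, length.out = bins + 1)[-1] - pi / bins
  wd <- function(x, c) abs(glycophase::wrapAngle(x - c))
  arcA <- glycophase::wrapAngle(centers - (-1.4)) > 0 &
    glycophase::wrapAngle(centers - (-1.4)) < 3.0
  g <- ifelse(arcA, 8 * wd(centers, 0.3)^2, 2 + 6 * wd(centers, 3.0)^2)
  list(centers = centers, g = g - min(g))
}

# small COLVAR file on disk
writeTempColvar <- function(lines) {
  f <- tempfile(fileext = ".dat")
  writeLines(lines, f)
  f
}

# identity basin maps (one basin per raw letter interval) for a set of
# dihedral columns: used when letter inheritance should reduce to the
# raw interval assignment
identityBasins <- function(columns) {
  entries <- lapply(columns, function(nm) {
    if (grepl("omega$", nm))
      list(minima = c(-1.3, 1.3, pi),
           boundaries = c(-2.62, 0, 2.62),
           letters = c("gg", "gt", "tg"), kind = "omega")
    else
      list(minima = c(-2.1, -1.0, 0, 1.0, 2.1, pi),
           boundaries = c(-2.62, -1.57, -0.52, 0.52, 1.57, 2.62),
           letters = c("A-", "G-", "C", "G+", "A+", "T"), kind = "phipsi")
  })
  names(entries) <- columns
  methods::new("BasinMap", entries = entries, bins = 72L,
               prominence = 0)
}
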