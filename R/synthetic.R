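#' @include AllClasses.R puckering.R colvar-io.R
NULL

#' Configure the synthetic glycan-trajectory generator
#'
#' Builds a validated generator configuration: a Markov chain over
#' conformer states with per-state circular dihedral distributions
#' (wrapped-normal noise, sd = 1/sqrt(kappa)), pucker states on the
#' (theta, phi) sphere, and a coupling c giving the probability that a
#' frame's pucker state is the partner of its conformer state rather
#' than a background draw.
#'
#' @param states list of conformer states; each a list with \code{name},
#'   \code{mean} (named radians per dihedral) and \code{kappa}.
#' @param transition row-stochastic transition matrix (states x states).
#' @param puckerStates list of pucker states; each a list with
#'   \code{name}, \code{theta}, \code{phi} (rad), \code{thetaSpread},
#'   \code{phiSpread} (rad).
#' @param pairing character vector naming, per conformer state, its
#'   partner pucker state.
#' @param coupling c in [0, 1].
#' @param background background pucker weights (default uniform).
#' @param nFrames default frame count (10^4).
#' @param Q ring puckering amplitude (Angstrom) for emitted geometries.
#' @param dihedrals dihedral names; default: those of the first state.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(states, transition, puckerStates, pairing,
                            coupling, background = NULL, nFrames = 10000L,
                            Q = 0.57, dihedrals = NULL) {
  if (is.null(dihedrals)) dihedrals <- names(states[[1]]$mean)
  if (is.null(background))
    background <- rep(1 / length(puckerStates), length(puckerStates))
  transition <- as.matrix(transition)
  new("SyntheticConfig", nFrames = as.integer(nFrames),
      dihedrals = dihedrals, states = states, transition = transition,
      puckerStates = puckerStates, pairing = pairing,
      background = background / sum(background),
      coupling = coupling, Q = Q)
}

# wrapped-normal draw around a circular mean
.rwrapped <- function(n, mean, sd) wrapAngle(stats::rnorm(n, mean, sd))

# theta noise reflected into [0, pi]
.reflectTheta <- function(x) {
  x <- x %% (2 * pi)
  ifelse(x > pi, 2 * pi - x, x)
}

#' Generate a synthetic glycan trajectory
#'
#' Draws a Markov chain over conformer states, per-frame dihedrals from
#' the state's wrapped-normal circular distributions, a pucker state
#' (partner of the conformer state with probability c, background draw
#' otherwise) and (theta, phi) around the pucker state's centre with
#' reflected/periodic wrapped spread. Fully reproducible from
#' \code{seed}.
#'
#' @param config a [SyntheticConfig-class].
#' @param nFrames frame count; defaults to the config's.
#' @param seed RNG seed (default 0).
#' @param dt frame spacing (ps) for the time column.
#' @return a [SyntheticTrajectory-class].
#' @export
simulateTrajectory <- function(config, nFrames = NULL, seed = 0, dt = 10) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (is.null(nFrames)) nFrames <- config@nFrames
  nFrames <- as.integer(nFrames)
  set.seed(seed)
  k <- length(config@states)
  stateNames <- vapply(config@states, `[[`, "", "name")
  pNames <- vapply(config@puckerStates, `[[`, "", "name")
  # Markov chain over conformer states, started from the stationary vector
  statio <- stationaryDistribution(config@transition)
  z <- integer(nFrames)
  z[1] <- sample.int(k, 1, prob = statio)
  if (nFrames > 1) {
    u <- stats::runif(nFrames - 1L)
    cums <- apply(config@transition, 1, cumsum)  # k x k, column = from
    for (t in 2:nFrames)
      z[t] <- findInterval(u[t - 1L], cums[, z[t - 1L]],
                           left.open = TRUE) + 1L
  }
  # dihedrals: wrapped-normal around the state-specific means
  vals <- matrix(NA_real_, nFrames, length(config@dihedrals) + 2L)
  colnames(vals) <- c(config@dihedrals, "theta", "phi")
  for (s in seq_len(k)) {
    idx <- which(z == s)
    if (!length(idx)) next
    st <- config@states[[s]]
    kap <- rep(st$kappa, length.out = length(config@dihedrals))
    for (j in seq_along(config@dihedrals))
      vals[idx, j] <- .rwrapped(length(idx),
                                st$mean[[config@dihedrals[j]]],
                                1 / sqrt(kap[j]))
  }
  # pucker state: partner with probability c, else background
  partnerIdx <- match(config@pairing, pNames)
  pz <- integer(nFrames)
  usePartner <- stats::runif(nFrames) < config@coupling
  pz[usePartner] <- partnerIdx[z[usePartner]]
  nBg <- sum(!usePartner)
  if (nBg)
    pz[!usePartner] <- sample.int(length(pNames), nBg, replace = TRUE,
                                  prob = config@background)
  for (s in seq_along(config@puckerStates)) {
    idx <- which(pz == s)
    if (!length(idx)) next
    ps <- config@puckerStates[[s]]
    vals[idx, "theta"] <- .reflectTheta(
      stats::rnorm(length(idx), ps$theta, ps$thetaSpread))
    # stored wrapped to (-pi, pi], the table-wide angle convention
    vals[idx, "phi"] <- wrapAngle(stats::rnorm(length(idx), ps$phi,
                                               ps$phiSpread))
  }
  cv <- colvarTable(time = (seq_len(nFrames) - 1) * dt, values = vals,
                    metadata = list(
                      source = "simulateTrajectory",
                      noise = "wrapped-normal",
                      seed = seed, coupling = config@coupling),
                    noWrap = c("theta", "phi"))
  new("SyntheticTrajectory", colvar = cv,
      conformerState = stateNames[z], puckerState = pNames[pz],
      config = config)
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P row-stochastic matrix.
#' @return stationary probability vector.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Emit ring geometries for the frames of a synthetic trajectory
#'
#' Bridges the generated (theta, phi) series to Cartesian ring
#' coordinates via [buildRing()], so that the forward Cremer-Pople
#' transform of every emitted geometry recovers the frame's pucker
#' coordinates.
#'
#' @param trajectory a [SyntheticTrajectory-class].
#' @param Q amplitude override (Angstrom); defaults to the config's.
#' @return list of 6 x 3 coordinate matrices, one per frame.
#' @export
emitRings <- function(trajectory, Q = NULL) {
  stopifnot(is(trajectory, "SyntheticTrajectory"))
  if (is.null(Q)) Q <- trajectory@config@Q
  v <- trajectory@colvar@values
  lapply(seq_len(nrow(v)), function(i)
    buildRing(Q, v[i, "theta"], v[i, "phi"]))
}

# shared branched test glycan: a 1-6 arm (phi/psi/omega) and a 1-3 arm
# (phi/psi) from one core residue -> 5 dihedrals, string
# "6- . . . 3- . ."
.presetDihedrals <- c("arm6.phi", "arm6.psi", "arm6.omega",
                      "arm3.phi", "arm3.psi")

#' Topology of the preset synthetic glycan
#'
#' A branched three-residue glycan: core residue with a 1-6 arm
#' (phi, psi, omega) and a 1-3 arm (phi, psi), giving five dihedrals and
#' the separator structure \code{6- ... 3- ...}.
#'
#' @return a [GlycanTopology-class].
#' @export
presetTopology <- function() {
  glycanTopology(data.frame(
    name = c("arm6", "arm3"),
    from = c("core", "core"),
    to = c("man6", "man3"),
    carbon = c(6L, 3L),
    hasOmega = c(TRUE, FALSE)))
}

#' Solution-regime generator preset
#'
#' Emulates a free glycan in water: several conformer states exchanging
#' on a Markov chain, pucker fixed in the chair basin near the theta = 0
#' pole, and zero conformer-pucker coupling, so conformer one-hot
#' columns and theta are uncorrelated up to sampling noise.
#'
#' @return a [SyntheticConfig-class].
#' @export
solutionPreset <- function() {
  d <- .presetDihedrals
  mk <- function(name, m) list(name = name,
                               mean = stats::setNames(m, d), kappa = 40)
  states <- list(
    mk("s1", c(0.0, 3.0, 1.0, 0.0, -1.0)),
    mk("s2", c(0.0, -1.0, 1.0, 0.0, -1.0)),
    mk("s3", c(1.0, 3.0, -1.2, 0.0, -1.0)),
    mk("s4", c(0.0, 3.0, 1.0, 2.0, 1.0)))
  trans <- matrix(0.02 / 3, 4, 4)
  diag(trans) <- 0.98
  pucker <- list(list(name = "chair", theta = 5 * pi / 180, phi = pi,
                      thetaSpread = 6 * pi / 180,
                      phiSpread = 60 * pi / 180))
  syntheticConfig(states, trans, pucker,
                  pairing = rep("chair", 4), coupling = 0,
                  nFrames = 10000L)
}

#' Bound-regime generator preset
#'
#' Emulates a glycan in a catalytic site: two dominant conformer states
#' whose designated linkage differs in psi/omega, strongly coupled
#' (c = 0.9) to two pucker states — the 4C1 chair pole partner of state
#' one, and an equatorial-band half-chair (theta = 54.7 deg, phi = 330
#' deg, the OH5 region) partner of state two. One-hot correlations of
#' the two states against theta then have opposite signs.
#'
#' @param coupling coupling c (default 0.9).
#' @return a [SyntheticConfig-class].
#' @export
boundPreset <- function(coupling = 0.9) {
  d <- .presetDihedrals
  mk <- function(name, m) list(name = name,
                               mean = stats::setNames(m, d), kappa = 40)
  states <- list(
    mk("s1", c(0.0, 3.0, 1.0, 0.0, -1.0)),     # chair-paired conformer
    mk("s2", c(2.0, -2.5, 2.8, 0.0, -1.0)))    # distortion-paired
  trans <- matrix(c(0.98, 0.02, 0.03, 0.97), 2, 2, byrow = TRUE)
  pucker <- list(
    list(name = "chair", theta = 5 * pi / 180, phi = pi,
         thetaSpread = 6 * pi / 180, phiSpread = 60 * pi / 180),
    list(name = "halfchair", theta = 54.7 * pi / 180, phi = 330 * pi / 180,
         thetaSpread = 7 * pi / 180, phiSpread = 10 * pi / 180))
  syntheticConfig(states, trans, pucker,
                  pairing = c("chair", "halfchair"), coupling = coupling,
                  nFrames = 10000L)
}

#' Write the hidden-state labels of a synthetic trajectory
#'
#' @param trajectory a [SyntheticTrajectory-class].
#' @param path output file (tab-separated: time, conformerState,
#'   puckerState).
#' @return \code{path}, invisibly.
#' @export
writeHiddenLabels <- function(trajectory, path) {
  stopifnot(is(trajectory, "SyntheticTrajectory"))
  df <- data.frame(time = trajectory@colvar@time,
                   conformerState = trajectory@conformerState,
                   puckerState = trajectory@puckerState)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
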