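#' @include AllClasses.R free-energy.R
NULL

#' Build a replica ladder for combined solute-tempering / bias-tempering
#'
#' Assembles the per-replica parameters of the enhanced-sampling
#' protocol: Hamiltonian scaling factors lambda (effective temperature
#' T0/lambda), well-tempered bias factors gamma (boosting temperature
#' dT = T0*(gamma - 1)), and Gaussian hill heights
#' h = (kB * dT / tau) * tauG. The ground replica (lambda = gamma = 1)
#' is unbiased with h = 0.
#'
#' Ladders may be given explicitly or generated as geometric progressions
#' between inclusive endpoints.
#'
#' @param T0 base temperature (K).
#' @param lambdas explicit non-increasing scaling factors starting at 1,
#'   or NULL to generate geometrically.
#' @param gammas explicit non-decreasing bias factors starting at 1, or
#'   NULL to generate geometrically.
#' @param nReplicas replica count for geometric generation.
#' @param lambdaMin,gammaMax geometric-progression endpoints (inclusive).
#' @param tau bias evolution time constant (ps).
#' @param tauG hill deposition stride (ps).
#' @param hillWidth Gaussian hill width (rad).
#' @return a [ReplicaLadder-class].
#' @examples
#' buildLadder(310.15, nReplicas = 12, lambdaMin = 0.42, gammaMax = 14)
#' @export
buildLadder <- function(T0 = 310.15, lambdas = NULL, gammas = NULL,
                        nReplicas = NULL, lambdaMin = NULL, gammaMax = NULL,
                        tau = 4, tauG = 1, hillWidth = 0.35) {
  if (T0 <= 0) stop("T0 must be positive")
  if (is.null(lambdas)) {
    if (is.null(nReplicas) || is.null(lambdaMin))
      stop("give lambdas, or nReplicas with lambdaMin")
    lambdas <- exp(seq(0, log(lambdaMin), length.out = nReplicas))
  }
  if (is.null(gammas)) {
    if (is.null(nReplicas) || is.null(gammaMax))
      stop("give gammas, or nReplicas with gammaMax")
    gammas <- exp(seq(0, log(gammaMax), length.out = nReplicas))
  }
  if (length(lambdas) != length(gammas))
    stop("lambda and gamma ladders must have equal length")
  if (any(lambdas > 1 + 1e-12)) stop("validation error: lambda > 1")
  if (any(gammas < 1 - 1e-12)) stop("validation error: gamma < 1")
  deltaT <- T0 * (gammas - 1)
  new("ReplicaLadder", T0 = T0, lambda = as.numeric(lambdas),
      gamma = as.numeric(gammas), teff = T0 / lambdas, deltaT = deltaT,
      height = kBoltzmann * deltaT / tau * tauG,
      tau = tau, tauG = tauG, hillWidth = hillWidth)
}

#' Well-tempered hill height
#'
#' h = (kB * T0 * (gamma - 1) / tau) * tauG, in kJ/mol: zero on the
#' unbiased ground replica (gamma = 1) and strictly increasing in gamma.
#'
#' @param T0 base temperature (K).
#' @param gamma bias factor(s), >= 1.
#' @param tau bias evolution time constant (ps).
#' @param tauG deposition stride (ps).
#' @return hill height(s) (kJ/mol).
#' @export
hillHeight <- function(T0, gamma, tau = 4, tauG = 1) {
  if (any(gamma < 1)) stop("gamma must be >= 1")
  kBoltzmann * T0 * (gamma - 1) / tau * tauG
}

#' The 16-replica ladder used for enzyme-bound glycans
#'
#' Explicit lambda ladder 1 .. 0.55 and gamma ladder 1 .. 6 (16 replicas)
#' with tau = 4 ps, tauG = 1 ps and 0.35 rad hills.
#'
#' @param T0 base temperature (K).
#' @return a [ReplicaLadder-class].
#' @export
boundLadder <- function(T0 = 310.15) {
  buildLadder(T0,
    lambdas = c(1, 0.98, 0.95, 0.92, 0.90, 0.87, 0.84, 0.81,
                0.78, 0.75, 0.72, 0.69, 0.65, 0.62, 0.58, 0.55),
    gammas = c(1, 1.13, 1.27, 1.43, 1.61, 1.82, 2.05, 2.31,
               2.60, 2.93, 3.30, 3.72, 4.19, 4.73, 5.32, 6))
}

#' The 12-replica geometric ladder used for free glycans in solution
#'
#' Geometric progressions of lambda between 1 and 0.42 and gamma between
#' 1 and 14 over 12 replicas.
#'
#' @param T0 base temperature (K).
#' @return a [ReplicaLadder-class].
#' @export
solutionLadder <- function(T0 = 310.15) {
  buildLadder(T0, nReplicas = 12, lambdaMin = 0.42, gammaMax = 14)
}

#' Validate a ladder against an expected effective-temperature range
#'
#' Checks the structural invariants (monotone lambda/gamma, unbiased
#' ground replica) and, when an expected range is supplied, compares the
#' realized effective-temperature span T0/lambda against it. A
#' discrepancy beyond \code{tol} Kelvin is surfaced as a warning, not
#' silently corrected: nominal ranges quoted for a ladder are sometimes
#' approximate labels inconsistent with the printed lambda endpoints.
#'
#' @param ladder a [ReplicaLadder-class].
#' @param expectedRange optional length-2 numeric, nominal (Tmin, Tmax).
#' @param tol tolerance in Kelvin (default 1).
#' @return invisibly, a list with \code{teffRange} and \code{ok}.
#' @export
validateLadder <- function(ladder, expectedRange = NULL, tol = 1) {
  stopifnot(is(ladder, "ReplicaLadder"))
  validObject(ladder)
  rng <- range(ladder@teff)
  ok <- TRUE
  if (!is.null(expectedRange)) {
    dev <- max(abs(rng - sort(expectedRange)))
    if (dev > tol) {
      ok <- FALSE
      warning(sprintf(
        "effective temperature range [%.1f, %.1f] K deviates from the nominal [%.1f, %.1f] K by %.1f K",
        rng[1], rng[2], min(expectedRange), max(expectedRange), dev))
    }
  }
  invisible(list(teffRange = rng, ok = ok))
}

#' Harmonic distance restraints of the enzyme/substrate complexes
#'
#' The four metal-coordination distance restraints applied to keep the
#' substrate in the binding site during enhanced sampling, with a force
#' constant of 150 kJ/mol per distance.
#'
#' @param complex \code{"MII"} (zinc site) or \code{"MI"} (calcium site).
#' @return data.frame with columns \code{atom1}, \code{atom2},
#'   \code{distance} (nm) and \code{k} (kJ mol^-1 nm^-2).
#' @export
bindingRestraints <- function(complex = c("MII", "MI")) {
  complex <- match.arg(complex)
  if (complex == "MII")
    data.frame(atom1 = rep("Zn2+", 4),
               atom2 = c("NE2_His90", "NE2_His471", "O2_Man4", "O3_Man4"),
               distance = c(0.50, 0.20, 0.40, 0.20), k = 150)
  else
    data.frame(atom1 = rep("Ca2+", 4),
               atom2 = c("O_Thr688", "OG1_Thr688", "O2_Man7", "O3_Man7"),
               distance = c(0.25, 0.25, 0.25, 0.25), k = 150)
}

#' Emit per-replica bias-engine input files
#'
#' Writes one deterministic plain-text configuration per replica: a
#' versioned header, the replica's lambda/gamma/hill height, one
#' well-tempered 1D bias action per dihedral (hill width and stride from
#' the ladder) and one harmonic restraint stanza per supplied distance.
#' The ground replica carries a zero-height bias. The dialect
#' round-trips through [parseBiasConfig()].
#'
#' @param ladder a [ReplicaLadder-class].
#' @param dihedrals character vector of biased dihedral names (>= 1).
#' @param restraints optional data.frame as from [bindingRestraints()].
#' @return named character vector, one config text per replica
#'   (\code{replica0}, \code{replica1}, ...).
#' @export
emitBiasConfig <- function(ladder, dihedrals, restraints = NULL) {
  stopifnot(is(ladder, "ReplicaLadder"))
  validObject(ladder)
  if (!length(dihedrals)) stop("at least one dihedral required")
  n <- length(ladder@lambda)
  out <- character(n)
  for (a in seq_len(n)) {
    ln <- c("# glycophase bias config v1",
            sprintf("REPLICA index=%d lambda=%.10g gamma=%.10g teff=%.10g",
                    a - 1L, ladder@lambda[a], ladder@gamma[a],
                    ladder@teff[a]))
    for (d in dihedrals)
      ln <- c(ln, sprintf(
        "METAD arg=%s height=%.10g width=%.10g stride_ps=%.10g tau_ps=%.10g",
        d, ladder@height[a], ladder@hillWidth, ladder@tauG, ladder@tau))
    if (!is.null(restraints) && nrow(restraints))
      for (i in seq_len(nrow(restraints)))
        ln <- c(ln, sprintf(
          "RESTRAINT atoms=%s,%s distance_nm=%.10g kappa=%.10g",
          restraints$atom1[i], restraints$atom2[i],
          restraints$distance[i], restraints$k[i]))
    out[a] <- paste(ln, collapse = "\n")
  }
  names(out) <- paste0("replica", seq_len(n) - 1L)
  out
}

#' Parse an emitted bias-engine configuration
#'
#' Inverse of [emitBiasConfig()] for a single replica's text.
#'
#' @param text one configuration string.
#' @return list with \code{replica}, \code{lambda}, \code{gamma},
#'   \code{teff}, \code{metad} (data.frame) and \code{restraints}
#'   (data.frame or NULL).
#' @export
parseBiasConfig <- function(text) {
  ln <- strsplit(text, "\n")[[1]]
  kv <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
    if (length(m) < 2) stop("malformed line: ", line)
    m[2]
  }
  rep_ln <- grep("^REPLICA ", ln, value = TRUE)
  if (length(rep_ln) != 1) stop("expected exactly one REPLICA line")
  metadLn <- grep("^METAD ", ln, value = TRUE)
  metad <- do.call(rbind, lapply(metadLn, function(l)
    data.frame(arg = kv(l, "arg"),
               height = as.numeric(kv(l, "height")),
               width = as.numeric(kv(l, "width")),
               stride_ps = as.numeric(kv(l, "stride_ps")),
               tau_ps = as.numeric(kv(l, "tau_ps")))))
  resLn <- grep("^RESTRAINT ", ln, value = TRUE)
  restr <- if (length(resLn)) do.call(rbind, lapply(resLn, function(l) {
    at <- strsplit(kv(l, "atoms"), ",")[[1]]
    data.frame(atom1 = at[1], atom2 = at[2],
               distance = as.numeric(kv(l, "distance_nm")),
               k = as.numeric(kv(l, "kappa")))
  })) else NULL
  list(replica = as.integer(kv(rep_ln, "index")),
       lambda = as.numeric(kv(rep_ln, "lambda")),
       gamma = as.numeric(kv(rep_ln, "gamma")),
       teff = as.numeric(kv(rep_ln, "teff")),
       metad = metad, restraints = restr)
}

#' Replica-exchange diagnostics
#'
#' From a per-attempt trace of walker positions on the replica ladder,
#' computes the acceptance probability of every neighbouring pair (the
#' fraction of attempts at which that pair swapped) and, per walker, the
#' round-trip times: the number of attempts needed to visit both ladder
#' ends and return to the starting end. Walkers with no completed round
#' trip are reported as censored.
#'
#' @param trace integer matrix, attempts x walkers; entry (t, w) is the
#'   replica index (0-based) occupied by walker w at attempt t.
#' @param checkPermutation require every attempt row to be a permutation
#'   of the replica indices (TRUE for real exchange traces; set FALSE for
#'   per-walker surrogate models).
#' @return list with \code{acceptance} (data.frame pair, rate),
#'   \code{roundTrips} (data.frame walker, mean, count), and
#'   \code{censored} (walkers without a completed round trip).
#' @export
exchangeDiagnostics <- function(trace, checkPermutation = TRUE) {
  trace <- as.matrix(trace)
  nAtt <- nrow(trace)
  nWalk <- ncol(trace)
  if (nAtt < 2) stop("need at least 2 attempts")
  nRep <- max(trace) + 1L
  if (nRep < 2) stop("need at least 2 replicas")
  if (min(trace) < 0) stop("data error: negative replica index")
  if (checkPermutation) {
    bad <- which(apply(trace, 1, function(r)
      !identical(sort(unique(r)), 0:(nRep - 1L)) || length(r) != nRep))
    if (length(bad))
      stop("data error: attempt row ", bad[1],
           " is not a permutation of replica indices")
  }
  # neighbour-pair swap counts: walker moved i -> i+1 while another i+1 -> i
  swaps <- numeric(nRep - 1L)
  prev <- trace[-nAtt, , drop = FALSE]
  cur <- trace[-1, , drop = FALSE]
  up <- prev + 1L == cur   # moved one rung up
  for (i in seq_len(nRep - 1L))
    swaps[i] <- sum(rowSums(up & prev == i - 1L) > 0)
  acc <- data.frame(pair = paste0(seq_len(nRep - 1L) - 1L, "-",
                                  seq_len(nRep - 1L)),
                    rate = swaps / (nAtt - 1L))
  # round trips per walker
  bottom <- 0L; top <- nRep - 1L
  rt <- vector("list", nWalk)
  for (w in seq_len(nWalk)) {
    x <- trace[, w]
    times <- integer(0)
    state <- 0L  # 0: waiting for an end; 1: went bottom, seek top; ...
    startAt <- NA_integer_; origin <- NA_integer_; seenOther <- FALSE
    for (t in seq_len(nAtt)) {
      if (is.na(origin)) {
        if (x[t] == bottom || x[t] == top) {
          origin <- x[t]; startAt <- t; seenOther <- FALSE
        }
      } else {
        other <- if (origin == bottom) top else bottom
        if (!seenOther && x[t] == other) seenOther <- TRUE
        else if (seenOther && x[t] == origin) {
          times <- c(times, t - startAt)
          origin <- x[t]; startAt <- t; seenOther <- FALSE
        }
      }
    }
    rt[[w]] <- times
  }
  counts <- lengths(rt)
  means <- vapply(rt, function(v) if (length(v)) mean(v) else NA_real_, 1)
  list(acceptance = acc,
       roundTrips = data.frame(walker = seq_len(nWalk), mean = means,
                               count = counts),
       censored = which(counts == 0))
}

#' Surrogate random-walk exchange traces
#'
#' Generates, per walker, an independent symmetric random walk on the
#' replica ladder: at every attempt the walker moves one rung up or down
#' with probability 1/2 each, staying put when the move would leave the
#' ladder (half-lazy reflecting ends). Under this model the mean one-way
#' passage 0 -> (n-1) takes (n-1)*n attempts, so a full round trip
#' averages 2*(n-1)*n attempts. Not a joint permutation across walkers;
#' analyse with \code{checkPermutation = FALSE}.
#'
#' @param nReplicas ladder size.
#' @param nAttempts attempts to simulate.
#' @param nWalkers number of independent walkers.
#' @return integer matrix attempts x walkers of 0-based replica indices.
#' @export
randomWalkTrace <- function(nReplicas, nAttempts, nWalkers = 1) {
  steps <- matrix(sample(c(-1L, 1L), nAttempts * nWalkers, replace = TRUE),
                  nAttempts, nWalkers)
  out <- matrix(0L, nAttempts, nWalkers)
  for (t in 2:nAttempts) {
    cand <- out[t - 1L, ] + steps[t, ]
    cand[cand < 0L | cand > nReplicas - 1L] <- out[t - 1L, ][
      cand < 0L | cand > nReplicas - 1L]
    out[t, ] <- cand
  }
  out
}
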