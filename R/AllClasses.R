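#' @import methods
NULL

#' Per-frame collective-variable table
#'
#' Container for time series of collective variables sampled along a
#' trajectory: glycosidic dihedrals (radians, wrapped to (-pi, pi]) and/or
#' Cremer-Pople pucker coordinates theta/phi.
#'
#' @slot time numeric vector of frame times (ps), strictly increasing.
#' @slot values numeric matrix, one named column per variable; rows align
#'   with \code{time}. Missing observations are \code{NA}.
#' @slot metadata list of free-form provenance entries.
#' @exportClass ColvarTable
setClass("ColvarTable",
  representation(time = "numeric", values = "matrix", metadata = "list"),
  prototype(time = numeric(0),
            values = matrix(numeric(0), 0, 0),
            metadata = list()))

setValidity("ColvarTable", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@time))
    msg <- c(msg, "number of value rows must equal length of time")
  if (ncol(object@values) > 0 && is.null(colnames(object@values)))
    msg <- c(msg, "value columns must be named")
  if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "duplicated variable names")
  if (length(msg)) msg else TRUE
})

#' Cremer-Pople pucker coordinates per frame
#'
#' @slot Q puckering amplitude (Angstrom), >= 0.
#' @slot theta polar angle in [0, pi] (radians); NA when Q = 0.
#' @slot phi azimuth in [0, 2*pi) (radians); 0 when undefined.
#' @slot definedPhi logical; FALSE near the poles (sin theta < 1e-6) where
#'   the azimuth is degenerate.
#' @exportClass PuckerCoords
setClass("PuckerCoords",
  representation(Q = "numeric", theta = "numeric", phi = "numeric",
                 definedPhi = "logical"))

setValidity("PuckerCoords", function(object) {
  n <- length(object@Q)
  if (length(object@theta) != n || length(object@phi) != n ||
      length(object@definedPhi) != n)
    return("all slots must have equal length")
  if (any(object@Q < 0, na.rm = TRUE)) return("Q must be >= 0")
  ok <- !is.na(object@theta)
  if (any(object@theta[ok] < -1e-12 | object@theta[ok] > pi + 1e-12))
    return("theta must lie in [0, pi]")
  TRUE
})

#' One-dimensional free-energy profile with block-averaged errors
#'
#' @slot centers bin centers (variable units).
#' @slot edges bin edges, length \code{length(centers) + 1}.
#' @slot deltaG free energy per bin (kJ/mol), global minimum shifted to 0;
#'   empty bins are \code{NA} (masked), never 0.
#' @slot sem standard error of the mean per bin (kJ/mol) from block
#'   averaging; \code{NA} where fewer than 2 blocks populate the bin.
#' @slot counts pooled occupancy per bin.
#' @slot effectiveBlocks number of blocks contributing per bin.
#' @slot temperature Kelvin.
#' @slot periodic logical; TRUE for angular variables on (-pi, pi].
#' @slot nBlocks number of blocks requested.
#' @exportClass FreeEnergyProfile
setClass("FreeEnergyProfile",
  representation(centers = "numeric", edges = "numeric", deltaG = "numeric",
                 sem = "numeric", counts = "numeric",
                 effectiveBlocks = "numeric", temperature = "numeric",
                 periodic = "logical", nBlocks = "integer"))

setValidity("FreeEnergyProfile", function(object) {
  msg <- character(0)
  nb <- length(object@centers)
  if (length(object@edges) != nb + 1) msg <- c(msg, "edges must be centers + 1")
  if (length(object@deltaG) != nb || length(object@sem) != nb ||
      length(object@counts) != nb)
    msg <- c(msg, "deltaG/sem/counts must match centers")
  g <- object@deltaG[!is.na(object@deltaG)]
  if (length(g) && abs(min(g)) > 1e-9)
    msg <- c(msg, "deltaG must be shifted so its minimum is 0")
  if (any(object@sem < 0, na.rm = TRUE)) msg <- c(msg, "sem must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional free-energy surface
#'
#' @slot xedges,yedges bin edges of the two variables.
#' @slot deltaG matrix (kJ/mol), minimum 0, empty cells \code{NA}.
#' @slot counts occupancy matrix.
#' @slot temperature Kelvin.
#' @slot xname,yname variable names.
#' @slot periodicX,periodicY periodicity flags.
#' @exportClass FreeEnergySurface
setClass("FreeEnergySurface",
  representation(xedges = "numeric", yedges = "numeric", deltaG = "matrix",
                 counts = "matrix", temperature = "numeric",
                 xname = "character", yname = "character",
                 periodicX = "logical", periodicY = "logical"))

setValidity("FreeEnergySurface", function(object) {
  msg <- character(0)
  if (!all(dim(object@deltaG) ==
           c(length(object@xedges) - 1L, length(object@yedges) - 1L)))
    msg <- c(msg, "deltaG dimensions must match bin edges")
  g <- object@deltaG[!is.na(object@deltaG)]
  if (length(g) && abs(min(g)) > 1e-9)
    msg <- c(msg, "deltaG minimum must be 0")
  if (length(msg)) msg else TRUE
})

#' Free-energy basin decomposition of periodic dihedral profiles
#'
#' One entry per dihedral: local minima of the 1D free-energy profile over
#' (-pi, pi], basin boundaries at the separating maxima, and the IUPAC
#' letter inherited by every angle inside each basin.
#'
#' @slot entries named list; each element a list with components
#'   \code{minima}, \code{boundaries}, \code{letters}, \code{kind}.
#' @slot bins number of profile bins used for detection.
#' @slot prominence minimum barrier depth (kJ/mol) for a retained minimum.
#' @exportClass BasinMap
setClass("BasinMap",
  representation(entries = "list", bins = "integer", prominence = "numeric"))

setValidity("BasinMap", function(object) {
  for (nm in names(object@entries)) {
    e <- object@entries[[nm]]
    need <- c("minima", "boundaries", "letters", "kind")
    if (!all(need %in% names(e)))
      return(sprintf("entry '%s' lacks %s", nm,
                     paste(setdiff(need, names(e)), collapse = ", ")))
    if (length(e$letters) != length(e$minima))
      return(sprintf("entry '%s': one letter per minimum required", nm))
    if (length(e$minima) > 1 && length(e$boundaries) != length(e$minima))
      return(sprintf("entry '%s': boundaries must alternate with minima", nm))
  }
  TRUE
})

#' Glycan linkage topology for conformer-string traversal
#'
#' @slot residues residue names.
#' @slot linkages data.frame with columns \code{name}, \code{from}
#'   (reducing side), \code{to}, \code{carbon} (linkage carbon x of the
#'   Ox-Cx bond) and \code{hasOmega}.
#' @slot root name of the free reducing-end residue where traversal starts.
#' @exportClass GlycanTopology
setClass("GlycanTopology",
  representation(residues = "character", linkages = "data.frame",
                 root = "character"))

setValidity("GlycanTopology", function(object) {
  lk <- object@linkages
  need <- c("name", "from", "to", "carbon", "hasOmega")
  if (!all(need %in% names(lk))) return("linkages must have name/from/to/carbon/hasOmega")
  if (!(object@root %in% object@residues)) return("root must be a residue")
  if (any(!c(lk$from, lk$to) %in% object@residues))
    return("linkage endpoints must be residues")
  if (anyDuplicated(lk$to)) return("each residue has at most one parent")
  TRUE
})

#' Per-frame conformer strings
#'
#' @slot strings character vector, one space-separated letter string per
#'   frame (\code{NA} for frames with missing angles).
#' @slot topology the GlycanTopology used for traversal.
#' @exportClass ConformerSeries
setClass("ConformerSeries",
  representation(strings = "character", topology = "GlycanTopology"))

#' Conformer population distribution
#'
#' @slot table data.frame with columns \code{string}, \code{count},
#'   \code{probability}, \code{shortLabel} (#1, #2, ... by descending
#'   probability; ties broken lexicographically). Conformers below the
#'   reporting threshold carry shortLabel "other".
#' @slot minProb reporting threshold (fraction).
#' @slot nFrames labelled frames used.
#' @exportClass ConformerDistribution
setClass("ConformerDistribution",
  representation(table = "data.frame", minProb = "numeric",
                 nFrames = "integer"))

setValidity("ConformerDistribution", function(object) {
  p <- object@table$probability
  if (length(p) && abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' PCA latent space over sin/cos dihedral features
#'
#' @slot scores frames x components score matrix.
#' @slot loadings features x components orthonormal loading matrix; the
#'   sign of each component is fixed so its largest-|loading| entry is
#'   positive.
#' @slot explained fraction of variance per component, non-increasing.
#' @slot center column means removed before rotation.
#' @slot tags per-frame dataset tag (for concatenated comparisons).
#' @exportClass LatentSpace
setClass("LatentSpace",
  representation(scores = "matrix", loadings = "matrix",
                 explained = "numeric", center = "numeric",
                 tags = "character"))

setValidity("LatentSpace", function(object) {
  if (nrow(object@scores) != length(object@tags))
    return("one tag per score row required")
  if (is.unsorted(-object@explained)) return("explained variance must be non-increasing")
  TRUE
})

#' Pairwise Pearson correlation matrix
#'
#' @slot r symmetric correlation matrix; undefined entries (constant
#'   columns) are \code{NA}, never 0.
#' @slot n number of frames used.
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(r = "matrix", n = "integer"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("matrix must be square")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) return("|r| must be <= 1")
  TRUE
})

#' Replica ladder for combined solute-tempering / bias-tempering sampling
#'
#' Per replica alpha: Hamiltonian scaling lambda (<= 1), well-tempered bias
#' factor gamma (>= 1), effective temperature T0/lambda, boosting
#' temperature dT = T0*(gamma - 1) and Gaussian hill height
#' h = (kB * dT / tau) * tauG.
#'
#' @slot T0 base temperature (K).
#' @slot lambda,gamma,teff,deltaT,height per-replica vectors.
#' @slot tau bias evolution time constant (ps).
#' @slot tauG hill deposition stride (ps).
#' @slot hillWidth Gaussian hill width (rad).
#' @exportClass ReplicaLadder
setClass("ReplicaLadder",
  representation(T0 = "numeric", lambda = "numeric", gamma = "numeric",
                 teff = "numeric", deltaT = "numeric", height = "numeric",
                 tau = "numeric", tauG = "numeric", hillWidth = "numeric"))

setValidity("ReplicaLadder", function(object) {
  msg <- character(0)
  n <- length(object@lambda)
  if (length(object@gamma) != n) msg <- c(msg, "lambda and gamma must match")
  if (any(object@lambda > 1 + 1e-12) || any(object@lambda <= 0))
    msg <- c(msg, "lambda must lie in (0, 1]")
  if (any(object@gamma < 1 - 1e-12)) msg <- c(msg, "gamma must be >= 1")
  if (n) {
    if (abs(object@lambda[1] - 1) > 1e-12) msg <- c(msg, "lambda[1] must be 1")
    if (abs(object@gamma[1] - 1) > 1e-12) msg <- c(msg, "gamma[1] must be 1")
    if (is.unsorted(-object@lambda)) msg <- c(msg, "lambda must be non-increasing")
    if (is.unsorted(object@gamma)) msg <- c(msg, "gamma must be non-decreasing")
    if (any(object@deltaT < -1e-12)) msg <- c(msg, "deltaT must be >= 0")
    if (any(object@height < -1e-12)) msg <- c(msg, "height must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Atom selection for dihedral and ring extraction from trajectories
#'
#' @slot rings named list; each element six ordered 1-based atom serials
#'   in ring order O5, C1, C2, C3, C4, C5.
#' @slot linkages named list; each element a list with \code{phi} and
#'   \code{psi} atom quadruples, an optional \code{omega} quadruple
#'   (1-6 / 2-6 linkages only) and the linkage \code{carbon}.
#' @exportClass SelectionConfig
setClass("SelectionConfig",
  representation(rings = "list", linkages = "list"))

setValidity("SelectionConfig", function(object) {
  for (nm in names(object@rings))
    if (length(object@rings[[nm]]) != 6L)
      return(sprintf("ring '%s' must name exactly 6 atoms", nm))
  for (nm in names(object@linkages)) {
    lk <- object@linkages[[nm]]
    if (length(lk$phi) != 4L || length(lk$psi) != 4L)
      return(sprintf("linkage '%s': phi/psi need 4 atom ids each", nm))
    if (!is.null(lk$omega) && length(lk$omega) != 4L)
      return(sprintf("linkage '%s': omega needs 4 atom ids", nm))
    quads <- list(lk$phi, lk$psi)
    if (!is.null(lk$omega)) quads <- c(quads, list(lk$omega))
    if (anyDuplicated(vapply(quads, paste, "", collapse = ",")))
      return(sprintf("linkage '%s': atom quadruples must be distinct", nm))
  }
  TRUE
})

#' Configuration of the synthetic glycan-trajectory generator
#'
#' Describes a hidden-Markov conformer process with per-state circular
#' dihedral distributions, a set of pucker states on the (theta, phi)
#' sphere, and a coupling c in [0, 1]: with probability c the frame's
#' pucker state is the one paired with the current conformer state,
#' otherwise it is drawn from the background weights.
#'
#' @slot nFrames default number of frames.
#' @slot dihedrals dihedral column names (e.g. "arm6.phi").
#' @slot states list of conformer states: \code{name}, \code{mean} (named
#'   radians per dihedral), \code{kappa} (concentration; wrapped-normal
#'   sd = 1/sqrt(kappa)).
#' @slot transition row-stochastic state transition matrix.
#' @slot puckerStates list: \code{name}, \code{theta}, \code{phi} (rad),
#'   \code{thetaSpread}, \code{phiSpread} (rad).
#' @slot pairing character; for each conformer state the name of its
#'   partner pucker state.
#' @slot background background pucker-state weights (sum 1).
#' @slot coupling c in [0, 1].
#' @slot Q ring puckering amplitude (Angstrom) for emitted geometries.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nFrames = "integer", dihedrals = "character",
                 states = "list", transition = "matrix",
                 puckerStates = "list", pairing = "character",
                 background = "numeric", coupling = "numeric",
                 Q = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  k <- length(object@states)
  if (k < 1) msg <- c(msg, "at least one conformer state required")
  if (length(object@puckerStates) < 1) msg <- c(msg, "at least one pucker state required")
  tm <- object@transition
  if (!all(dim(tm) == c(k, k))) msg <- c(msg, "transition matrix must be k x k")
  else if (any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
    msg <- c(msg, "transition matrix rows must be non-negative and sum to 1")
  if (object@coupling < 0 || object@coupling > 1)
    msg <- c(msg, "coupling must lie in [0, 1]")
  if (length(object@pairing) != k)
    msg <- c(msg, "pairing must name one pucker state per conformer state")
  pnames <- vapply(object@puckerStates, `[[`, "", "name")
  if (length(object@pairing) == k && !all(object@pairing %in% pnames))
    msg <- c(msg, "pairing must reference defined pucker states")
  if (abs(sum(object@background) - 1) > 1e-9 || any(object@background < 0))
    msg <- c(msg, "background weights must be a probability vector")
  for (s in object@states) {
    if (!all(object@dihedrals %in% names(s$mean)))
      msg <- c(msg, sprintf("state '%s' lacks means for all dihedrals", s$name))
    if (any(s$kappa <= 0)) msg <- c(msg, "concentrations must be > 0")
  }
  if (object@Q < 0) msg <- c(msg, "Q must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic trajectory with known hidden states
#'
#' @slot colvar the generated ColvarTable (dihedrals + theta + phi).
#' @slot conformerState hidden conformer-state name per frame.
#' @slot puckerState hidden pucker-state name per frame.
#' @slot config the generating SyntheticConfig.
#' @exportClass SyntheticTrajectory
setClass("SyntheticTrajectory",
  representation(colvar = "ColvarTable", conformerState = "character",
                 puckerState = "character", config = "SyntheticConfig"))

setValidity("SyntheticTrajectory", function(object) {
  n <- length(object@colvar@time)
  if (length(object@conformerState) != n || length(object@puckerState) != n)
    return("hidden state labels must have one entry per frame")
  TRUE
})
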