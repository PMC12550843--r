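#' @include AllClasses.R free-energy.R
NULL

# IUPAC letter intervals on (-pi, pi]. Ownership convention (audited once,
# applied everywhere): intervals are half-open and closed at the lower
# bound, with T owning exactly [+2.62, pi] and (-pi, -2.62], and tg
# likewise for omega.
.phiPsiBreaks <- c(-2.62, -1.57, -0.52, 0.52, 1.57, 2.62)
.phiPsiLetters <- c("A-", "G-", "C", "G+", "A+")  # between successive breaks
.omegaBreaks <- c(-2.62, 0, 2.62)
.omegaLetters <- c("gg", "gt")

#' IUPAC letter of a dihedral angle
#'
#' Maps angles to the IUPAC conformer letters. For phi/psi:
#' C = (-0.52, +0.52), G+ = (+0.52, +1.57), A+ = (+1.57, +2.62),
#' T = [+2.62, pi] or (-pi, -2.62), A- = (-2.62, -1.57),
#' G- = (-1.57, -0.52). For omega: gg = (-2.62, 0), gt = (0, 2.62),
#' tg = [2.62, pi] or (-pi, -2.62]. Boundary values belong to the
#' interval whose printed lower bound they equal, with T / tg owning
#' both +/-2.62 endpoints.
#'
#' @param angle angles in radians, wrapped to (-pi, pi].
#' @param kind \code{"phipsi"} (default) or \code{"omega"}.
#' @return character vector of letters.
#' @examples
#' letterForAngle(0)            # "C"
#' letterForAngle(3.0)          # "T"
#' letterForAngle(1.0, "omega") # "gt"
#' @export
letterForAngle <- function(angle, kind = c("phipsi", "omega")) {
  kind <- match.arg(kind)
  if (any(angle <= -pi - 1e-12 | angle > pi + 1e-12, na.rm = TRUE))
    stop("angles must be wrapped to (-pi, pi]")
  out <- rep(NA_character_, length(angle))
  ok <- !is.na(angle)
  if (kind == "phipsi") {
    wrapT <- ok & (angle >= 2.62 | angle <= -2.62)
    out[wrapT] <- "T"
    inner <- ok & !wrapT
    idx <- findInterval(angle[inner], .phiPsiBreaks, left.open = FALSE)
    out[inner] <- .phiPsiLetters[idx]
  } else {
    wrapT <- ok & (angle >= 2.62 | angle <= -2.62)
    out[wrapT] <- "tg"
    inner <- ok & !wrapT
    idx <- findInterval(angle[inner], .omegaBreaks, left.open = FALSE)
    out[inner] <- .omegaLetters[idx]
  }
  out
}

#' Free-energy basins of a periodic dihedral profile
#'
#' Identifies the local minima of a periodic 1D free-energy profile that
#' exceed a prominence threshold, places basin boundaries at the maxima
#' separating adjacent retained minima, and labels each basin with the
#' IUPAC letter of its minimum's interval. Every angle in a basin then
#' inherits the basin letter, which is the defining behaviour of the
#' conformer-string classification: an angle may lie in one letter's raw
#' interval yet be assigned the neighbouring letter because it belongs to
#' that letter's free-energy basin.
#'
#' Shallow minima are merged watershed-style: while the smallest barrier
#' separating two adjacent minima is less than \code{prominence}, the
#' shallower minimum is absorbed into its neighbour.
#'
#' @param profile a periodic [FreeEnergyProfile-class] over (-pi, pi]
#'   (see [feProfile1D()]), or a numeric vector of free energies on a
#'   uniform periodic grid.
#' @param kind letter table to use, \code{"phipsi"} or \code{"omega"}.
#' @param prominence minimum barrier (kJ/mol) for a distinct basin;
#'   default one kB*T at the profile temperature.
#' @param temperature used for the default prominence when \code{profile}
#'   is a bare vector.
#' @return list with \code{minima} (radians), \code{boundaries}
#'   (radians; empty for a single basin spanning the circle),
#'   \code{letters}, and \code{kind} — one [BasinMap-class] entry.
#' @export
findBasins <- function(profile, kind = c("phipsi", "omega"),
                       prominence = NULL, temperature = 310.15) {
  kind <- match.arg(kind)
  if (is(profile, "FreeEnergyProfile")) {
    g <- profile@deltaG
    centers <- profile@centers
    temperature <- profile@temperature
  } else {
    g <- as.numeric(profile)
    centers <- seq(-pi, pi, length.out = length(g) + 1)[-1] -
      pi / length(g)
  }
  if (is.null(prominence)) prominence <- kBoltzmann * temperature
  n <- length(g)
  if (sum(!is.na(g)) < 2) stop("profile needs at least 2 populated bins")
  # treat masked (unsampled) bins as high free energy: they are barriers
  gg <- g
  gg[is.na(gg)] <- max(g, na.rm = TRUE) + 10 * prominence
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  isMin <- gg < gg[nxt] & gg <= gg[prv]
  mins <- which(isMin)
  if (!length(mins) || (max(gg) - min(gg)) < prominence) {
    # flat (or single-basin) profile: one basin covering the circle
    return(list(minima = centers[which.min(gg)], boundaries = numeric(0),
                letters = letterForAngle(centers[which.min(gg)], kind),
                kind = kind))
  }
  # separating barrier between adjacent minima (circular order)
  barrier <- function(i1, i2) {  # max g on the arc i1 -> i2 (exclusive)
    idx <- if (i2 > i1) seq(i1, i2) else c(seq(i1, n), seq(1, i2))
    k <- idx[which.max(gg[idx])]
    c(height = gg[k], at = k)
  }
  repeat {
    if (length(mins) == 1L) break
    k <- length(mins)
    bh <- numeric(k)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      bh[i] <- barrier(mins[i], mins[j])["height"]
    }
    depth <- numeric(k)  # shallowest side of each barrier
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      depth[i] <- bh[i] - max(gg[mins[i]], gg[mins[j]])
    }
    w <- which.min(depth)
    if (depth[w] >= prominence) break
    j <- if (w == k) 1L else w + 1L
    drop <- if (gg[mins[w]] >= gg[mins[j]]) w else j
    mins <- mins[-drop]
  }
  mins <- sort(mins)
  k <- length(mins)
  if (k == 1L)
    return(list(minima = centers[mins], boundaries = numeric(0),
                letters = letterForAngle(centers[mins], kind), kind = kind))
  bounds <- numeric(k)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    bounds[i] <- centers[barrier(mins[i], mins[j])["at"]]
  }
  list(minima = centers[mins], boundaries = wrapAngle(bounds),
       letters = letterForAngle(centers[mins], kind), kind = kind)
}

#' Build the basin map of every configured dihedral
#'
#' Computes a periodic 72-bin free-energy profile per dihedral column and
#' decomposes each into letter-labelled basins via [findBasins()].
#'
#' @param table a [ColvarTable-class].
#' @param dihedrals character vector of dihedral column names; omega
#'   columns are those ending in \code{".omega"}.
#' @param bins profile bins (default 72, i.e. 5-degree resolution).
#' @param prominence basin prominence threshold (kJ/mol); default 1 kB*T.
#' @param temperature Kelvin.
#' @return a [BasinMap-class].
#' @export
basinMap <- function(table, dihedrals = NULL, bins = 72,
                     prominence = NULL, temperature = 310.15) {
  stopifnot(is(table, "ColvarTable"))
  if (is.null(dihedrals))
    dihedrals <- grep("\\.(phi|psi|omega)$", colnames(table@values),
                      value = TRUE)
  if (!length(dihedrals)) stop("no dihedral columns found")
  if (is.null(prominence)) prominence <- kBoltzmann * temperature
  entries <- list()
  for (nm in dihedrals) {
    kind <- if (grepl("\\.omega$", nm)) "omega" else "phipsi"
    prof <- feProfile1D(table@values[, nm], bins = bins,
                        temperature = temperature, nBlocks = 5,
                        periodic = TRUE)
    entries[[nm]] <- findBasins(prof, kind = kind, prominence = prominence)
  }
  new("BasinMap", entries = entries, bins = as.integer(bins),
      prominence = prominence)
}

#' Letter assigned to an angle under a basin decomposition
#'
#' @param angle angles (radians, wrapped).
#' @param basin one [BasinMap-class] entry (list with minima, boundaries,
#'   letters).
#' @return character vector of inherited basin letters.
#' @export
basinLetter <- function(angle, basin) {
  k <- length(basin$minima)
  if (k == 1L) {
    out <- rep(basin$letters, length(angle))
    out[is.na(angle)] <- NA_character_
    return(out)
  }
  # boundaries[i] separates minima i and i+1 (circularly); an angle
  # belongs to the basin whose bounding arc contains it
  b <- sort(basin$boundaries)
  # map each sorted boundary back to its separating position, then locate
  idx <- findInterval(angle, b)  # 0..k ; 0 and k are the same wrap arc
  # basin of arc (b[i], b[i+1]) is the minimum inside it
  mins <- basin$minima
  arcOf <- integer(k)
  mi <- findInterval(mins, b)
  mi[mi == 0L] <- k
  arcOf[mi] <- seq_len(k)  # arc index -> minimum index
  idx[idx == 0L] <- k
  out <- basin$letters[arcOf[idx]]
  out[is.na(angle)] <- NA_character_
  out
}

#' Define a glycan linkage topology
#'
#' @param linkages data.frame with columns \code{name}, \code{from} (the
#'   residue on the reducing side), \code{to}, \code{carbon} (the linkage
#'   carbon x of the Ox-Cx bond at the branch origin) and \code{hasOmega}
#'   (TRUE for 1-6 / 2-6 linkages).
#' @param root the free reducing-end residue; defaults to the unique
#'   residue that is never a \code{to}.
#' @return a [GlycanTopology-class].
#' @export
glycanTopology <- function(linkages, root = NULL) {
  linkages <- as.data.frame(linkages, stringsAsFactors = FALSE)
  residues <- unique(c(linkages$from, linkages$to))
  if (is.null(root)) {
    cand <- setdiff(linkages$from, linkages$to)
    if (length(cand) != 1)
      stop("cannot infer a unique free reducing end; give `root`")
    root <- cand
  }
  new("GlycanTopology", residues = residues, linkages = linkages,
      root = root)
}

#' Read a glycan topology from a YAML file
#'
#' The schema is a top-level \code{linkages} list whose entries carry
#' \code{name}, \code{from}, \code{to}, \code{carbon} and
#' \code{hasOmega}, plus an optional top-level \code{root}.
#'
#' @param path YAML file.
#' @return a [GlycanTopology-class].
#' @export
readGlycanTopology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  lk <- do.call(rbind, lapply(y$linkages, function(l)
    data.frame(name = l$name, from = l$from, to = l$to,
               carbon = as.integer(l$carbon),
               hasOmega = isTRUE(l$hasOmega))))
  glycanTopology(lk, root = y$root)
}

# depth-first traversal: at each junction emit the separator "x-" and
# descend the higher-carbon branch to its terminus before the lower one.
# Returns a data.frame of tokens: type "sep" or "dihedral".
.traversalPlan <- function(topology) {
  lk <- topology@linkages
  out <- list()
  visit <- function(res) {
    children <- lk[lk$from == res, , drop = FALSE]
    if (!nrow(children)) return()
    children <- children[order(-children$carbon), , drop = FALSE]
    junction <- nrow(children) > 1
    for (i in seq_len(nrow(children))) {
      ch <- children[i, ]
      if (junction)
        out[[length(out) + 1]] <<- data.frame(
          type = "sep", token = sprintf("%d-", ch$carbon),
          column = NA_character_, kind = NA_character_)
      angles <- c("phi", "psi", if (ch$hasOmega) "omega")
      for (ang in angles)
        out[[length(out) + 1]] <<- data.frame(
          type = "dihedral", token = NA_character_,
          column = paste(ch$name, ang, sep = "."),
          kind = if (ang == "omega") "omega" else "phipsi")
      visit(ch$to)
    }
  }
  visit(topology@root)
  do.call(rbind, out)
}

#' Assign per-frame conformer strings
#'
#' Builds the letter string of every frame: starting at the free reducing
#' end, the traversal emits for each linkage the basin letters of phi,
#' psi and (when present) omega in this order; at branching junctions a
#' separator named after the branch-origin carbon (e.g. \code{6-}) is
#' inserted and the higher-carbon branch is followed to its terminus
#' before the lower branch. Letters are inherited from free-energy
#' basins ([basinMap()]), not raw intervals. Frames with a missing angle
#' are labelled \code{NA} and excluded from distributions.
#'
#' @param table a [ColvarTable-class] with the dihedral columns named
#'   \code{<linkage>.<angle>}.
#' @param basins a [BasinMap-class] covering every traversed dihedral.
#' @param topology a [GlycanTopology-class].
#' @return a [ConformerSeries-class].
#' @export
assignConformers <- function(table, basins, topology) {
  stopifnot(is(table, "ColvarTable"), is(basins, "BasinMap"),
            is(topology, "GlycanTopology"))
  plan <- .traversalPlan(topology)
  need <- plan$column[plan$type == "dihedral"]
  missingCols <- setdiff(need, colnames(table@values))
  if (length(missingCols))
    stop("table lacks dihedral column(s): ",
         paste(missingCols, collapse = ", "))
  missingBasins <- setdiff(need, names(basins@entries))
  if (length(missingBasins))
    stop("basin map lacks entries for: ",
         paste(missingBasins, collapse = ", "))
  n <- length(table@time)
  parts <- matrix("", n, nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (plan$type[i] == "sep") parts[, i] <- plan$token[i]
    else parts[, i] <- basinLetter(table@values[, plan$column[i]],
                                   basins@entries[[plan$column[i]]])
  }
  strings <- apply(parts, 1, paste, collapse = " ")
  strings[apply(parts, 1, anyNA)] <- NA_character_
  new("ConformerSeries", strings = strings, topology = topology)
}

#' Conformer population distribution
#'
#' Normalized histogram over the distinct conformer strings of a series.
#' Short labels #1, #2, ... are assigned by descending probability, ties
#' broken by lexicographic string order. Conformers below \code{minProb}
#' keep their row but are short-labelled \code{"other"}.
#'
#' @param series a [ConformerSeries-class] or character vector of strings.
#' @param minProb reporting threshold as a fraction (default 0.05, the
#'   conventional 5 percent cut for dominant conformers).
#' @return a [ConformerDistribution-class].
#' @export
conformerDistribution <- function(series, minProb = 0.05) {
  s <- if (is(series, "ConformerSeries")) series@strings else series
  s <- s[!is.na(s)]
  if (!length(s)) stop("no labelled frames")
  tab <- table(s)
  df <- data.frame(string = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$probability <- df$count / sum(df$count)
  df <- df[order(-df$probability, df$string), , drop = FALSE]
  major <- df$probability >= minProb
  df$shortLabel <- ifelse(major, paste0("#", cumsum(major)), "other")
  rownames(df) <- NULL
  new("ConformerDistribution",
      table = df[, c("string", "count", "probability", "shortLabel")],
      minProb = minProb, nFrames = length(s))
}

#' Moving-average conformer populations over time
#'
#' Convergence diagnostic: the moving-average fraction of each top
#' conformer along the trajectory, with a flag that is TRUE when the
#' drift of each average across the last quartile of frames is below
#' \code{tol}.
#'
#' @param series a [ConformerSeries-class] or character vector.
#' @param window moving-average window in frames (>= 1); \code{window = 1}
#'   returns the raw indicator series.
#' @param nTop number of top-ranked conformers tracked.
#' @param tol convergence tolerance on the last-quartile drift (absolute
#'   fraction).
#' @return list with \code{frames} (centre indices), \code{average}
#'   (matrix, one column per tracked conformer), \code{converged}
#'   (named logical).
#' @export
populationTimeseries <- function(series, window, nTop = 3, tol = 0.05) {
  s <- if (is(series, "ConformerSeries")) series@strings else series
  n <- length(s)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window exceeds series length")
  dist <- conformerDistribution(s, minProb = 0)
  top <- utils::head(dist@table$string, nTop)
  avg <- sapply(top, function(cf) {
    ind <- as.numeric(!is.na(s) & s == cf)
    as.numeric(stats::filter(ind, rep(1 / window, window), sides = 1))
  })
  avg <- matrix(avg, ncol = length(top),
                dimnames = list(NULL, top))
  frames <- seq_len(n)
  valid <- frames >= window
  lastQ <- frames > n - ceiling(n / 4) & valid
  converged <- apply(avg, 2, function(a) {
    aa <- a[lastQ & !is.na(a)]
    length(aa) > 1 && (max(aa) - min(aa)) < tol
  })
  list(frames = frames[valid],
       average = avg[valid, , drop = FALSE], converged = converged)
}
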