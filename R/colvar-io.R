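#' @include AllClasses.R
NULL

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' The package-wide wrapping convention: the interval is half-open at
#' -pi, so -pi maps to pi and pi stays pi. Applied to every angle column
#' at ingest; all downstream math assumes it.
#'
#' @param x numeric angles (radians).
#' @return wrapped angles in (-pi, pi].
#' @examples
#' wrapAngle(3.30)   # 3.30 - 2*pi
#' wrapAngle(-pi)    # pi
#' @export
wrapAngle <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Construct a collective-variable table
#'
#' @param time frame times (ps).
#' @param values numeric matrix or data.frame of variables, one named
#'   column each.
#' @param metadata list of provenance entries.
#' @param wrap names of angle columns to wrap to (-pi, pi]; by default all
#'   columns except pucker \code{theta} (already in [0, pi]) and any
#'   column named in \code{noWrap}.
#' @param noWrap columns exempt from wrapping.
#' @return a [ColvarTable-class].
#' @export
colvarTable <- function(time, values, metadata = list(),
                        wrap = NULL, noWrap = c("theta", "Q")) {
  values <- as.matrix(as.data.frame(values, check.names = FALSE))
  storage.mode(values) <- "double"
  if (is.null(wrap)) wrap <- setdiff(colnames(values), noWrap)
  for (nm in intersect(wrap, colnames(values)))
    values[, nm] <- wrapAngle(values[, nm])
  if (length(time) > 1 && any(diff(time) <= 0, na.rm = TRUE))
    warning("time is not strictly increasing")
  new("ColvarTable", time = as.numeric(time), values = values,
      metadata = metadata)
}

#' Read a COLVAR-style whitespace table
#'
#' Parses the plain-text column-table dialect written by collective-
#' variable engines: a header line \code{#! FIELDS time <names>} followed
#' by whitespace-separated numeric rows. Additional \code{#!} metadata
#' lines and blank lines are skipped. Angle columns are wrapped to
#' (-pi, pi] on ingest; unknown columns are preserved verbatim.
#'
#' @param path file path.
#' @param noWrap column names exempt from wrapping (default: pucker theta
#'   and amplitude Q).
#' @return a [ColvarTable-class].
#' @export
readColvar <- function(path, noWrap = c("theta", "Q")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty file: ", path)
  hdr <- grep("^#!\\s*FIELDS\\b", lines)
  if (!length(hdr)) stop("parse error: missing '#! FIELDS' header: ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS\\s*", "", lines[hdr[1]])),
                     "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("parse error: no data rows: ", path)
  rows <- strsplit(trimws(body), "\\s+")
  nf <- lengths(rows)
  bad <- which(nf != length(fields))
  if (length(bad))
    stop(sprintf("parse error: ragged row at data line %d (%d fields, expected %d)",
                 bad[1], nf[bad[1]], length(fields)))
  tok <- unlist(rows)
  num <- suppressWarnings(as.numeric(tok))
  badTok <- is.na(num) & !(toupper(tok) %in% c("NA", "NAN"))
  if (any(badTok))
    stop("parse error: non-numeric value '", tok[which(badTok)[1]],
         "' in ", path)
  vals <- matrix(num, ncol = length(fields), byrow = TRUE)
  colnames(vals) <- fields
  tcol <- if ("time" %in% fields) "time" else fields[1]
  colvarTable(time = vals[, tcol],
              values = vals[, setdiff(fields, tcol), drop = FALSE],
              metadata = list(source = path), noWrap = noWrap)
}

#' Write a collective-variable table in COLVAR dialect
#'
#' Emits a \code{#! FIELDS time <names>} header and full-precision
#' (17 significant digits) whitespace rows, so that
#' \code{readColvar(writeColvar(x))} reproduces the numeric content
#' exactly.
#'
#' @param x a [ColvarTable-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeColvar <- function(x, path) {
  stopifnot(is(x, "ColvarTable"))
  m <- cbind(time = x@time, x@values)
  txt <- apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(paste("#! FIELDS", paste(colnames(m), collapse = " ")), txt),
             path)
  invisible(path)
}

#' Signed dihedral angle of atom quadruples
#'
#' Standard signed torsion: for atoms a-b-c-d, the angle between the
#' planes (a,b,c) and (b,c,d), measured with the IUPAC sign convention,
#' in (-pi, pi]. A planar cis quadruple gives 0, trans gives pi.
#' Quadruples containing collinear triples (undefined torsion) return
#' \code{NA}.
#'
#' @param a,b,c,d numeric length-3 vectors or n x 3 matrices.
#' @return numeric vector of angles (rad), \code{NA} where undefined.
#' @export
dihedralAngle <- function(a, b, c, d) {
  asm <- function(v) if (is.matrix(v)) v else matrix(v, 1, 3)
  a <- asm(a); b <- asm(b); c <- asm(c); d <- asm(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  crs <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                              u[, 3] * v[, 1] - u[, 1] * v[, 3],
                              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- crs(b1, b2)
  n2 <- crs(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(crs(n1, n2) * b2) / b2n
  deg <- rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20 | b2n < 1e-10
  out <- atan2(y, x)
  out[out <= -pi] <- pi
  out[deg] <- NA_real_
  out
}

#' Read an atom-selection configuration
#'
#' Parses a YAML selection file naming, per monitored ring, the six
#' ordered ring atoms (O5, C1, C2, C3, C4, C5) and, per glycosidic
#' linkage, the phi/psi (and omega for 1-6 / 2-6 linkages) atom
#' quadruples. Atom identifiers are 1-based serial numbers, following the
#' PDB convention.
#'
#' @param path YAML file with top-level keys \code{rings} and
#'   \code{linkages}; each linkage has \code{phi}, \code{psi}, optional
#'   \code{omega} (4 integers each) and \code{carbon}.
#' @return a [SelectionConfig-class].
#' @export
readSelectionConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  rings <- lapply(y$rings, function(r) as.integer(unlist(r)))
  linkages <- lapply(y$linkages, function(l) {
    out <- list(phi = as.integer(unlist(l$phi)),
                psi = as.integer(unlist(l$psi)),
                carbon = if (is.null(l$carbon)) NA_integer_
                         else as.integer(l$carbon))
    if (!is.null(l$omega)) out$omega <- as.integer(unlist(l$omega))
    out
  })
  new("SelectionConfig", rings = rings, linkages = linkages)
}

#' Extract dihedral and pucker variables from trajectory coordinates
#'
#' Computes, for every frame, the configured glycosidic dihedrals (signed
#' torsion, (-pi, pi]) and the Cremer-Pople (Q, theta, phi) of every
#' configured ring, producing the same table the COLVAR reader ingests.
#'
#' @param xyz per-frame coordinates: an n_frames x (3 * n_atoms) matrix
#'   (bio3d xyz layout) or a list of n_atoms x 3 matrices.
#' @param config a [SelectionConfig-class]; atom identifiers are 1-based
#'   serials into the coordinate set.
#' @param time frame times (ps); defaults to 0, 1, 2, ...
#' @return a [ColvarTable-class] with one column per dihedral
#'   (\code{<linkage>.phi} etc.) and, per ring, \code{<ring>.Q},
#'   \code{<ring>.theta}, \code{<ring>.phi}. Frames with undefined
#'   (collinear) torsions carry \code{NA} in that column.
#' @export
extractVariables <- function(xyz, config, time = NULL) {
  stopifnot(is(config, "SelectionConfig"))
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- t(vapply(xyz, function(m) as.numeric(t(m)),
                    numeric(3 * nrow(xyz[[1]]))))
  nAtoms <- ncol(xyz) %/% 3L
  nfr <- nrow(xyz)
  allIds <- unlist(c(config@rings,
                     lapply(config@linkages, function(l)
                       c(l$phi, l$psi, l$omega))))
  bad <- unique(allIds[allIds < 1L | allIds > nAtoms])
  if (length(bad))
    stop("configuration error: atom id(s) not in topology: ",
         paste(bad, collapse = ", "))
  at <- function(id) xyz[, (3 * (id - 1L) + 1L):(3 * id), drop = FALSE]
  cols <- list()
  for (nm in names(config@linkages)) {
    lk <- config@linkages[[nm]]
    for (ang in intersect(c("phi", "psi", "omega"), names(lk))) {
      q <- lk[[ang]]
      cols[[paste(nm, ang, sep = ".")]] <-
        dihedralAngle(at(q[1]), at(q[2]), at(q[3]), at(q[4]))
    }
  }
  for (nm in names(config@rings)) {
    ids <- config@rings[[nm]]
    rings <- lapply(seq_len(nfr), function(i)
      matrix(xyz[i, as.vector(rbind(3 * (ids - 1L) + 1L,
                                    3 * (ids - 1L) + 2L,
                                    3 * ids))], 6, 3, byrow = TRUE))
    pc <- cremerPople(rings)
    cols[[paste(nm, "Q", sep = ".")]] <- pc@Q
    cols[[paste(nm, "theta", sep = ".")]] <- pc@theta
    cols[[paste(nm, "phi", sep = ".")]] <- pc@phi
  }
  if (is.null(time)) time <- seq_len(nfr) - 1
  vals <- do.call(cbind, cols)
  colnames(vals) <- names(cols)
  thetaCols <- grep("\\.(theta|Q)$", colnames(vals), value = TRUE)
  puckPhi <- grep("\\.phi$", colnames(vals), value = TRUE)
  puckPhi <- puckPhi[sub("\\.phi$", ".theta", puckPhi) %in% thetaCols]
  colvarTable(time, vals, metadata = list(source = "extracted"),
              noWrap = c(thetaCols, puckPhi))
}
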