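#' @include AllClasses.R
NULL

#' Boltzmann constant in kJ/(mol K)
#' @export
kBoltzmann <- 0.0083144626

#' Convert probabilities to free energies
#'
#' Applies delta-G = -kB * T * ln(P). Zero probabilities yield \code{NA}
#' (masked), never a finite value.
#'
#' @param P probabilities in [0, 1].
#' @param temperature Kelvin (default 310.15).
#' @return free energies (kJ/mol); \code{NA} where P = 0.
#' @examples
#' probabilityToFE(1)                      # 0
#' probabilityToFE(0.2) - probabilityToFE(0.8)  # kB*T*ln 4
#' @export
probabilityToFE <- function(P, temperature = 310.15) {
  if (any(P < 0 | P > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  out <- -kBoltzmann * temperature * log(P)
  out[!is.na(P) & P == 0] <- NA_real_
  out
}

#' Block-averaging statistics
#'
#' Sampling statistics of a set of per-block means X_j: the grand mean,
#' the variance of the sampling distribution
#' var = (N/(N-1)) * (mean(X^2) - mean(X)^2), and the standard error of
#' the mean sem = sqrt(var / N). Blocks are treated as independent;
#' correlation within blocks is controlled by the caller's choice of block
#' count.
#'
#' @param blockMeans numeric vector of per-block means (NA blocks are
#'   dropped; the effective count is reported).
#' @return list with \code{n}, \code{mean}, \code{var}, \code{sem}.
#' @export
blockStats <- function(blockMeans) {
  x <- blockMeans[!is.na(blockMeans)]
  n <- length(x)
  if (n < 2) return(list(n = n, mean = if (n) mean(x) else NA_real_,
                         var = NA_real_, sem = NA_real_))
  v <- (n / (n - 1)) * (mean(x^2) - mean(x)^2)
  v <- max(v, 0)  # guard against negative rounding at zero variance
  list(n = n, mean = mean(x), var = v, sem = sqrt(v / n))
}

# shared binning helper: counts per bin given explicit edges
.binCounts <- function(x, edges) {
  x <- x[!is.na(x)]
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[x == edges[1]] <- 1L  # lowest edge belongs to the first bin
  tabulate(idx[idx >= 1L & idx <= length(edges) - 1L],
           nbins = length(edges) - 1L)
}

#' One-dimensional free-energy profile with block-averaged errors
#'
#' Bins a sampled series, converts pooled bin probabilities to free
#' energies via delta-G = -kB*T*ln(P), and estimates per-bin standard
#' errors by splitting the series into \code{nBlocks} contiguous blocks,
#' computing a free-energy value per block and bin, and applying the
#' block-averaging formulas of [blockStats()]. Bins empty in a given
#' block contribute a masked block value (dropped, with the effective
#' block count recorded). The profile is shifted so its global minimum
#' is zero.
#'
#' @param x sampled values (NA dropped).
#' @param bins number of bins, or a vector of explicit bin edges.
#' @param temperature Kelvin.
#' @param nBlocks number of evenly sized blocks (typically 5 to 10);
#'   must be >= 2.
#' @param range limits of the binning window; defaults to
#'   \code{c(-pi, pi)} when \code{periodic} else the data range.
#' @param periodic TRUE for angular variables on (-pi, pi].
#' @return a [FreeEnergyProfile-class].
#' @export
feProfile1D <- function(x, bins = 72, temperature = 310.15, nBlocks = 5,
                        range = NULL, periodic = FALSE) {
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 2) stop("nBlocks must be >= 2 (variance undefined)")
  keep <- !is.na(x)
  xs <- x[keep]
  if (!length(xs)) stop("no finite observations")
  if (length(bins) > 1) edges <- sort(bins)
  else {
    if (is.null(range))
      range <- if (periodic) c(-pi, pi)
               else grDevices::extendrange(xs, f = 1e-9)
    edges <- seq(range[1], range[2], length.out = bins + 1)
  }
  nb <- length(edges) - 1L
  if (length(xs) < nBlocks * nb)
    warning("fewer samples than nBlocks * bins; block errors will be noisy")
  counts <- .binCounts(xs, edges)
  P <- counts / sum(counts)
  dG <- probabilityToFE(P, temperature)
  dG <- dG - min(dG, na.rm = TRUE)
  # per-block free energies (block-wise normalized, unshifted)
  blk <- cut(seq_along(xs), breaks = nBlocks, labels = FALSE)
  bg <- matrix(NA_real_, nBlocks, nb)
  for (j in seq_len(nBlocks)) {
    cj <- .binCounts(xs[blk == j], edges)
    pj <- cj / sum(cj)
    gj <- rep(NA_real_, nb)
    pos <- pj > 0
    gj[pos] <- -kBoltzmann * temperature * log(pj[pos])
    bg[j, ] <- gj
  }
  sem <- effN <- numeric(nb)
  for (b in seq_len(nb)) {
    st <- blockStats(bg[, b])
    sem[b] <- st$sem
    effN[b] <- st$n
  }
  sem[counts == 0] <- NA_real_
  new("FreeEnergyProfile",
      centers = (edges[-1] + edges[-length(edges)]) / 2,
      edges = edges, deltaG = dG, sem = sem, counts = as.numeric(counts),
      effectiveBlocks = effN, temperature = temperature,
      periodic = periodic, nBlocks = nBlocks)
}

#' Two-dimensional free-energy surface
#'
#' Bins two equal-length series on a rectangular grid (200 x 200 for
#' pucker theta/phi landscapes, 35 x 35 for PCA latent spaces), converts
#' cell probabilities to free energies and shifts the minimum to zero.
#' Empty cells are masked (\code{NA}) and excluded from minima searches.
#' For periodic variables the binning window covers one full period so
#' basins crossing the seam stay contiguous after wrapping.
#'
#' @param x,y sampled values (frames with NA in either are dropped).
#' @param bins length-2 integer vector of bin counts.
#' @param temperature Kelvin.
#' @param xrange,yrange binning windows; default to the data range, or to
#'   the full period for periodic variables.
#' @param periodicX,periodicY periodicity flags; periodic ranges default
#'   to (-pi, pi].
#' @param xname,yname variable names carried into the object.
#' @return a [FreeEnergySurface-class].
#' @export
feSurface2D <- function(x, y, bins = c(200L, 200L), temperature = 310.15,
                        xrange = NULL, yrange = NULL,
                        periodicX = FALSE, periodicY = FALSE,
                        xname = "x", yname = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(bins) == 1) bins <- rep(bins, 2)
  if (is.null(xrange))
    xrange <- if (periodicX) c(-pi, pi) else grDevices::extendrange(x, f = 1e-9)
  if (is.null(yrange))
    yrange <- if (periodicY) c(-pi, pi) else grDevices::extendrange(y, f = 1e-9)
  xe <- seq(xrange[1], xrange[2], length.out = bins[1] + 1)
  ye <- seq(yrange[1], yrange[2], length.out = bins[2] + 1)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, left.open = TRUE)
  ix[x == xe[1]] <- 1L
  iy <- findInterval(y, ye, rightmost.closed = TRUE, left.open = TRUE)
  iy[y == ye[1]] <- 1L
  ok <- ix >= 1 & ix <= bins[1] & iy >= 1 & iy <= bins[2]
  counts <- matrix(tabulate((iy[ok] - 1L) * bins[1] + ix[ok],
                            nbins = bins[1] * bins[2]),
                   bins[1], bins[2])
  if (sum(counts) == 0) stop("no populated cells")
  P <- counts / sum(counts)
  dG <- matrix(NA_real_, bins[1], bins[2])
  pos <- P > 0
  dG[pos] <- -kBoltzmann * temperature * log(P[pos])
  dG <- dG - min(dG, na.rm = TRUE)
  new("FreeEnergySurface", xedges = xe, yedges = ye, deltaG = dG,
      counts = counts, temperature = temperature,
      xname = xname, yname = yname,
      periodicX = periodicX, periodicY = periodicY)
}

#' Write a free-energy profile as a tab-separated table
#'
#' @param x a [FreeEnergyProfile-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(x, path) {
  stopifnot(is(x, "FreeEnergyProfile"))
  df <- data.frame(center = x@centers, deltaG = x@deltaG, sem = x@sem,
                   count = x@counts, blocks = x@effectiveBlocks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# free-energy profile, T = %.6g K, %d blocks",
                     x@temperature, x@nBlocks), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a free-energy surface as a dense grid table
#'
#' One-line header with the bin edges, then the delta-G grid (rows = the
#' first variable's bins); masked cells are written as NA.
#'
#' @param x a [FreeEnergySurface-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(x, path) {
  stopifnot(is(x, "FreeEnergySurface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s edges: %s", x@xname,
            paste(formatC(x@xedges, format = "g", digits = 10), collapse = " ")),
    sprintf("# %s edges: %s", x@yname,
            paste(formatC(x@yedges, format = "g", digits = 10), collapse = " "))),
    con)
  utils::write.table(formatC(x@deltaG, format = "g", digits = 10), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
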