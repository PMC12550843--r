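#' @include AllClasses.R free-energy.R
NULL

#' Periodicity-aware sin/cos dihedral features
#'
#' Expands each dihedral column into an interleaved (sin, cos) pair,
#' which represents the angle on the unit circle and so accounts for
#' dihedral periodicity. Frames containing a missing angle are dropped
#' (with a message).
#'
#' @param table a [ColvarTable-class].
#' @param dihedrals dihedral column names; defaults to all columns
#'   matching \code{.phi/.psi/.omega} suffixes.
#' @param tag dataset tag attached to every frame (for concatenated
#'   comparisons).
#' @return numeric matrix with columns \code{<name>.sin},
#'   \code{<name>.cos} and attributes \code{tag} (per-row dataset tag)
#'   and \code{frames} (kept frame indices).
#' @export
featurize <- function(table, dihedrals = NULL, tag = "dataset") {
  stopifnot(is(table, "ColvarTable"))
  if (is.null(dihedrals))
    dihedrals <- grep("\\.(phi|psi|omega)$", colnames(table@values),
                      value = TRUE)
  if (!length(dihedrals)) stop("no dihedral columns to featurize")
  missingCols <- setdiff(dihedrals, colnames(table@values))
  if (length(missingCols))
    stop("unknown dihedral column(s): ", paste(missingCols, collapse = ", "))
  ang <- table@values[, dihedrals, drop = FALSE]
  keep <- stats::complete.cases(ang)
  if (any(!keep))
    message(sum(!keep), " frame(s) with missing angles dropped")
  ang <- ang[keep, , drop = FALSE]
  out <- matrix(0, nrow(ang), 2L * ncol(ang))
  cn <- character(2L * ncol(ang))
  for (i in seq_len(ncol(ang))) {
    out[, 2 * i - 1] <- sin(ang[, i])
    out[, 2 * i] <- cos(ang[, i])
    cn[2 * i - 1] <- paste0(dihedrals[i], ".sin")
    cn[2 * i] <- paste0(dihedrals[i], ".cos")
  }
  colnames(out) <- cn
  attr(out, "tag") <- rep(tag, nrow(out))
  attr(out, "frames") <- which(keep)
  out
}

#' PCA latent space over concatenated feature matrices
#'
#' Concatenates the supplied feature matrices row-wise (so that datasets
#' being compared share one latent space), removes the column means of
#' the concatenated matrix, and rotates onto principal components.
#' Features are centred but not variance-scaled: sin/cos features are
#' already commensurate. The sign of each component is fixed so that its
#' largest-|loading| entry is positive.
#'
#' @param datasets a single feature matrix from [featurize()] or a list
#'   of them with identical columns.
#' @return a [LatentSpace-class].
#' @export
fitLatent <- function(datasets) {
  if (is.matrix(datasets)) datasets <- list(datasets)
  cols <- colnames(datasets[[1]])
  for (i in seq_along(datasets)) {
    ci <- colnames(datasets[[i]])
    if (!identical(ci, cols)) {
      off <- union(setdiff(ci, cols), setdiff(cols, ci))
      if (!length(off)) off <- "(column order differs)"
      stop("feature columns mismatch across datasets: ",
           paste(off, collapse = ", "))
    }
  }
  tags <- unlist(lapply(seq_along(datasets), function(i) {
    tg <- attr(datasets[[i]], "tag")
    if (is.null(tg)) rep(paste0("dataset", i), nrow(datasets[[i]])) else tg
  }))
  X <- do.call(rbind, datasets)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sgn <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  rot <- sweep(rot, 2, sgn, `*`)
  sc <- sweep(pc$x, 2, sgn, `*`)
  ev <- pc$sdev^2
  new("LatentSpace", scores = sc, loadings = rot,
      explained = ev / sum(ev), center = pc$center, tags = tags)
}

#' Free-energy surface in the latent space
#'
#' 35 x 35 free-energy surface over (PC1, PC2) for the frames carrying a
#' given dataset tag. Binning windows span the concatenated scores so
#' surfaces of different tags are directly comparable.
#'
#' @param space a [LatentSpace-class].
#' @param tag dataset tag to select; \code{NULL} uses all frames.
#' @param temperature Kelvin.
#' @param bins bin counts (default 35 x 35).
#' @param components which two components to bin (default 1:2).
#' @return a [FreeEnergySurface-class].
#' @export
latentFES <- function(space, tag = NULL, temperature = 310.15,
                      bins = c(35L, 35L), components = 1:2) {
  stopifnot(is(space, "LatentSpace"))
  sel <- if (is.null(tag)) rep(TRUE, nrow(space@scores))
         else space@tags == tag
  if (!any(sel)) stop("unknown dataset tag: ", tag)
  sc <- space@scores
  xr <- grDevices::extendrange(sc[, components[1]], f = 1e-9)
  yr <- grDevices::extendrange(sc[, components[2]], f = 1e-9)
  feSurface2D(sc[sel, components[1]], sc[sel, components[2]], bins = bins,
              temperature = temperature, xrange = xr, yrange = yr,
              xname = paste0("PC", components[1]),
              yname = paste0("PC", components[2]))
}

#' One-hot encoding of conformer labels
#'
#' Converts ordinal conformer labels into a binary matrix, one column per
#' included conformer. Labels outside the included set give an all-zero
#' row (logged via message); row sums are therefore 0 or 1.
#'
#' @param labels a [ConformerSeries-class] or character vector.
#' @param include conformers to encode; defaults to all observed labels
#'   with population at least \code{minProb}.
#' @param minProb population filter used when \code{include} is NULL
#'   (default 0.01; rare conformers give noise-dominated correlations).
#' @return binary numeric matrix, rows = frames (NA rows for missing
#'   labels).
#' @export
oneHot <- function(labels, include = NULL, minProb = 0.01) {
  s <- if (is(labels, "ConformerSeries")) labels@strings else labels
  if (is.null(include)) {
    d <- conformerDistribution(s, minProb = 0)@table
    include <- sort(d$string[d$probability >= minProb])
  }
  if (!length(include)) stop("empty conformer label set")
  out <- matrix(0, length(s), length(include),
                dimnames = list(NULL, include))
  out[is.na(s), ] <- NA_real_
  for (j in seq_along(include)) out[, j] <- as.numeric(s == include[j])
  outside <- sum(!is.na(s) & !(s %in% include))
  if (outside) message(outside, " frame(s) outside the included set (zero rows)")
  out
}

#' Pairwise Pearson correlation across variable blocks
#'
#' Column-binds any combination of feature matrices, one-hot conformer
#' matrices and named numeric series (e.g. pucker theta) and computes the
#' pairwise Pearson correlation matrix over frames complete in all
#' blocks. Constant columns give \code{NA} entries (with a warning),
#' never 0.
#'
#' @param ... matrices and/or named numeric vectors with equal row
#'   counts.
#' @return a [CorrelationMatrix-class].
#' @examples
#' th <- runif(100); x <- cbind(a = th + rnorm(100, 0, 0.1))
#' correlatePhase(x, theta = th)
#' @export
correlatePhase <- function(...) {
  blocks <- list(...)
  nms <- names(blocks)
  cols <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (is.null(dim(b))) {
      b <- matrix(b, ncol = 1,
                  dimnames = list(NULL, if (!is.null(nms) && nzchar(nms[i]))
                    nms[i] else paste0("v", i)))
    }
    cols[[i]] <- as.matrix(b)
  }
  n <- unique(vapply(cols, nrow, 1L))
  if (length(n) != 1) stop("row counts differ across blocks")
  M <- do.call(cbind, cols)
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  if (nrow(M) < 3) stop("need at least 3 complete frames")
  sds <- apply(M, 2, stats::sd)
  r <- suppressWarnings(stats::cor(M, method = "pearson"))
  if (any(sds == 0)) {
    warning("constant column(s): ",
            paste(colnames(M)[sds == 0], collapse = ", "),
            " - correlations undefined (NA)")
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  new("CorrelationMatrix", r = r, n = nrow(M))
}
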