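#' @include AllClasses.R puckering.R
NULL

#' Plot a 1D free-energy profile with block-error bars
#'
#' @param x a [FreeEnergyProfile-class].
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotProfile <- function(x, xlab = "variable", ylab = expression(
  Delta * G ~ "(kJ/mol)"), main = NULL, ...) {
  stopifnot(is(x, "FreeEnergyProfile"))
  ok <- !is.na(x@deltaG)
  graphics::plot(x@centers[ok], x@deltaG[ok], type = "l",
                 xlab = xlab, ylab = ylab, main = main, ...)
  up <- x@deltaG[ok] + x@sem[ok]
  lo <- x@deltaG[ok] - x@sem[ok]
  graphics::arrows(x@centers[ok], lo, x@centers[ok], up, length = 0.02,
                   angle = 90, code = 3, col = "grey50")
  invisible(NULL)
}

#' Mollweide map of a pucker free-energy surface
#'
#' Projects a (theta, phi) free-energy surface with the equal-area
#' Mollweide map and draws it as filled cell polygons, with the
#' canonical shape labels overlaid. Masked cells are capped for display
#' at max(deltaG) + 2 kJ/mol (cosmetic only).
#'
#' @param surface a [FreeEnergySurface-class] whose x variable is theta
#'   in [0, pi] and y variable phi.
#' @param centerPhi central meridian (rad).
#' @param labels overlay canonical shape labels (default TRUE).
#' @param palette colour ramp function.
#' @return invisibly, NULL.
#' @export
plotMollweideFES <- function(surface, centerPhi = pi, labels = TRUE,
                             palette = grDevices::hcl.colors) {
  stopifnot(is(surface, "FreeEnergySurface"))
  g <- surface@deltaG
  cap <- max(g, na.rm = TRUE) + 2
  g[is.na(g)] <- cap
  nx <- nrow(g); ny <- ncol(g)
  cols <- palette(64, "viridis")[pmin(
    64L, 1L + floor(63 * g / cap))]
  graphics::plot(NA, xlim = c(-2 * sqrt(2), 2 * sqrt(2)),
                 xlab = "", ylab = "", axes = FALSE, asp = 1,
                 ylim = c(-sqrt(2), sqrt(2)))
  te <- surface@xedges; pe <- surface@yedges
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    crn <- mollweide(c(te[i], te[i + 1], te[i + 1], te[i]),
                     c(pe[j], pe[j], pe[j + 1], pe[j + 1]), centerPhi)
    graphics::polygon(crn$x, crn$y, col = cols[(j - 1L) * nx + i],
                      border = NA)
  }
  if (labels) {
    tab <- canonicalShapes()
    xy <- mollweide(tab$theta, tab$phi, centerPhi)
    graphics::text(xy$x, xy$y, tab$label, cex = 0.55, col = "white")
  }
  invisible(NULL)
}
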