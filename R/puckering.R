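#' @include AllClasses.R
NULL

# Ring order is fixed as [O5, C1, C2, C3, C4, C5]; with the mean-plane
# normal taken from the two weighted coordinate sums in this order, the
# 4C1 chair of D-pyranoses sits at the theta = 0 pole.
.ringOrder <- c("O5", "C1", "C2", "C3", "C4", "C5")

#' Cremer-Pople puckering coordinates of six-membered rings
#'
#' Computes the puckering amplitude Q, polar angle theta and azimuth phi of
#' one or more six-membered rings from Cartesian coordinates. The
#' construction follows the standard recipe: translate the ring to its
#' geometric centre, define the mean plane through the two weighted
#' coordinate sums, project out-of-plane displacements z_j, and obtain
#' (q2, phi2) from the m = 2 Fourier sums and q3 from the alternating sum.
#' Then Q = sqrt(q2^2 + q3^2), theta = acos(q3/Q), phi = phi2 in [0, 2*pi).
#'
#' Ring atoms must be supplied in the order O5, C1, C2, C3, C4, C5. Under
#' this convention the 4C1 chair of D-pyranoses lies at theta near 0 and
#' 1C4 at theta near pi.
#'
#' @param ring a 6 x 3 numeric matrix of coordinates (Angstrom), or a
#'   list of such matrices for many frames.
#' @return a [PuckerCoords-class] object (one frame per ring). Planar
#'   rings (Q < 1e-8) yield Q = 0 with theta/phi flagged undefined;
#'   near-pole frames (sin theta < 1e-6) have \code{definedPhi = FALSE}
#'   and phi reported as 0.
#' @examples
#' hex <- buildRing(Q = 0)          # planar hexagon
#' cremerPople(hex)                  # Q = 0, angles undefined
#' cremerPople(buildRing(0.57, theta = 0.1, phi = 1))
#' @export
cremerPople <- function(ring) {
  if (is.matrix(ring)) ring <- list(ring)
  n <- length(ring)
  Q <- theta <- phi <- numeric(n)
  defined <- logical(n)
  for (i in seq_len(n)) {
    xyz <- ring[[i]]
    if (!is.matrix(xyz) || any(dim(xyz) != c(6L, 3L)))
      stop("each ring must be a 6 x 3 coordinate matrix")
    if (anyNA(xyz)) { Q[i] <- NA; theta[i] <- NA; phi[i] <- NA; next }
    cp <- .cpSingle(xyz)
    Q[i] <- cp[1]; theta[i] <- cp[2]; phi[i] <- cp[3]
  }
  planar <- !is.na(Q) & Q < 1e-8
  Q[planar] <- 0
  theta[planar] <- NA_real_
  phi[planar] <- NA_real_
  defined <- !is.na(theta) & sin(pmin(pmax(theta, 0), pi)) >= 1e-6
  phi[!is.na(theta) & !defined] <- 0
  phi[is.na(theta)] <- 0
  new("PuckerCoords", Q = Q, theta = theta, phi = phi, definedPhi = defined)
}

.cpSingle <- function(xyz) {
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  j <- 0:5
  ang <- 2 * pi * j / 6
  R1 <- colSums(rel * sin(ang))
  R2 <- colSums(rel * cos(ang))
  nrm <- c(R1[2] * R2[3] - R1[3] * R2[2],
           R1[3] * R2[1] - R1[1] * R2[3],
           R1[1] * R2[2] - R1[2] * R2[1])
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-12) return(c(0, NA_real_, NA_real_))  # collinear sums
  nrm <- nrm / nl
  z <- drop(rel %*% nrm)
  q2cos <- sqrt(1 / 3) * sum(z * cos(2 * ang))
  q2sin <- -sqrt(1 / 3) * sum(z * sin(2 * ang))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2cos^2 + q2sin^2)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < 1e-8) return(c(Q, NA_real_, NA_real_))
  theta <- acos(pmin(pmax(q3 / Q, -1), 1))
  phi <- atan2(q2sin, q2cos) %% (2 * pi)
  c(Q, theta, phi)
}

#' Build a ring geometry with prescribed pucker coordinates
#'
#' Inverse of [cremerPople()]: applies the Cremer-Pople out-of-plane
#' displacement pattern z_j(Q, theta, phi) to a regular planar reference
#' hexagon. The forward transform of the result recovers (Q, theta, phi)
#' exactly (phi up to the 2*pi wrap, and arbitrary at the poles).
#'
#' @param Q puckering amplitude (Angstrom), >= 0.
#' @param theta polar angle (rad) in [0, pi].
#' @param phi azimuth (rad).
#' @param radius radius of the reference hexagon (Angstrom); the default
#'   1.46 gives bond lengths typical of pyranose rings.
#' @return 6 x 3 coordinate matrix in ring order O5, C1, C2, C3, C4, C5.
#' @export
buildRing <- function(Q, theta = 0, phi = 0, radius = 1.46) {
  if (Q < 0) stop("Q must be >= 0")
  j <- 0:5
  ang <- 2 * pi * j / 6
  q2 <- Q * sin(theta)
  q3 <- Q * cos(theta)
  z <- sqrt(1 / 3) * q2 * cos(phi + 2 * ang) + sqrt(1 / 6) * q3 * (-1)^j
  # the mean-plane normal of this construction points along -z, so the
  # Cartesian displacement carries the opposite sign of the target z_j
  xyz <- cbind(radius * cos(ang), radius * sin(ang), -z)
  rownames(xyz) <- .ringOrder
  xyz
}

# 38 canonical shapes on the (theta, phi) sphere: chairs at the poles,
# boats/skew-boats alternating every 30 deg on the equator, envelopes and
# half-chairs alternating every 30 deg on the two tropics at
# theta = acos(1/sqrt(3)) and pi - acos(1/sqrt(3)). Order matters: ties in
# canonicalName() are broken by the earlier entry.
.canonicalTable <- local({
  d <- pi / 180
  ttrop <- acos(1 / sqrt(3))
  eq <- c("3,OB", "3S1", "B1,4", "5S1", "2,5B", "2SO",
          "B3,O", "1S3", "1,4B", "1S5", "B2,5", "OS2")
  north <- c("OE", "OH1", "E1", "2H1", "2E", "2H3",
             "E3", "4H3", "4E", "4H5", "E5", "OH5")
  south <- c("3E", "3H4", "E4", "5H4", "5E", "5HO",
             "EO", "1HO", "1E", "1H2", "E2", "3H2")
  data.frame(
    label = c("4C1", "1C4", eq, north, south),
    theta = c(0, pi, rep(pi / 2, 12), rep(ttrop, 12), rep(pi - ttrop, 12)),
    phi = c(0, 0, rep(seq(0, 330, by = 30) * d, 3)),
    stringsAsFactors = FALSE)
})

#' Canonical pucker reference shapes
#'
#' The 38 canonical six-membered-ring shapes and their reference positions
#' on the Cremer-Pople sphere: 2 chairs at the poles, 6 boats and 6
#' skew-boats alternating every 30 degrees of phi on the equator, and 12
#' envelopes plus 12 half-chairs alternating on the tropics at
#' theta = 54.74 / 125.26 degrees.
#'
#' @return data.frame with columns \code{label}, \code{theta}, \code{phi}
#'   (radians). Row order is the documented tie-break order of
#'   [canonicalName()].
#' @export
canonicalShapes <- function() .canonicalTable

#' Name ring shapes by the nearest canonical reference
#'
#' Assigns each (theta, phi) pucker state the IUPAC label of the canonical
#' shape at minimal great-circle distance on the sphere. Ties are broken
#' by the order of [canonicalShapes()]. Planar frames (Q = 0 /
#' undefined theta) receive the sentinel label \code{"planar"}.
#'
#' @param x a [PuckerCoords-class] object, or a numeric vector of theta
#'   values (radians) when \code{phi} is given.
#' @param phi azimuth values (radians) when \code{x} is numeric.
#' @return character vector of shape labels.
#' @examples
#' canonicalName(0.03, 1.0)   # near the north pole: "4C1"
#' canonicalName(pi / 2, 300 * pi / 180)  # "B2,5"
#' @export
canonicalName <- function(x, phi = NULL) {
  if (is(x, "PuckerCoords")) {
    theta <- x@theta
    ph <- x@phi
  } else {
    theta <- as.numeric(x)
    ph <- as.numeric(phi)
    if (length(ph) != length(theta)) stop("theta and phi lengths differ")
  }
  tab <- .canonicalTable
  out <- rep("planar", length(theta))
  ok <- !is.na(theta)
  if (any(ok)) {
    # great-circle distance on the unit sphere
    ct <- cos(theta[ok]); st <- sin(theta[ok])
    cosd <- outer(ct, cos(tab$theta)) +
      outer(st, sin(tab$theta)) * cos(outer(ph[ok], tab$phi, `-`))
    cosd <- pmin(pmax(cosd, -1), 1)
    # max cos = min distance; which.max returns the first (earlier entry)
    idx <- apply(round(cosd, 12), 1, which.max)
    out[ok] <- tab$label[idx]
  }
  out
}

#' Mollweide equal-area projection of the pucker sphere
#'
#' Maps (theta, phi) to planar (x, y) with the pseudocylindrical
#' equal-area Mollweide projection used for pucker landscapes: latitude
#' = pi/2 - theta, longitude = phi - centerPhi wrapped to (-pi, pi], and
#' the auxiliary angle t solved iteratively from
#' 2 t + sin(2 t) = pi * sin(latitude).
#'
#' @param theta polar angle(s) in [0, pi] (rad).
#' @param phi azimuth(s) (rad).
#' @param centerPhi central meridian (rad); the default pi keeps the
#'   whole equator visible without a seam through the B2,5 / OS2 region.
#' @param tol convergence tolerance on the auxiliary-angle residual.
#' @return data.frame with columns \code{x} in [-2*sqrt(2), 2*sqrt(2)]
#'   and \code{y} in [-sqrt(2), sqrt(2)]; the poles map to the y extremes.
#' @export
mollweide <- function(theta, phi, centerPhi = pi, tol = 1e-12) {
  if (any(theta < -1e-9 | theta > pi + 1e-9, na.rm = TRUE))
    stop("theta must lie in [0, pi]")
  lat <- pi / 2 - theta
  lon <- (phi - centerPhi + pi) %% (2 * pi) - pi
  lon[lon == -pi] <- pi
  t <- .mollweideAux(lat, tol)
  data.frame(x = 2 * sqrt(2) / pi * lon * cos(t), y = sqrt(2) * sin(t))
}

# Solve 2t + sin 2t = pi sin(lat) for the auxiliary angle t. The left side
# is monotone on [-pi/2, pi/2], so vectorized bisection is unconditionally
# convergent (including near the poles where Newton stalls on the flat
# derivative); two Newton polish steps sharpen the residual below tol.
.mollweideAux <- function(lat, tol = 1e-12) {
  t <- lat
  pole <- !is.na(lat) & abs(abs(lat) - pi / 2) < 1e-12
  t[pole] <- sign(lat[pole]) * pi / 2
  act <- which(!pole & !is.na(lat))
  if (length(act)) {
    target <- pi * sin(lat[act])
    lo <- rep(-pi / 2, length(act))
    hi <- rep(pi / 2, length(act))
    for (iter in 1:80) {
      mid <- (lo + hi) / 2
      up <- (2 * mid + sin(2 * mid)) < target
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    tt <- (lo + hi) / 2
    for (iter in 1:2) {
      f <- 2 * tt + sin(2 * tt) - target
      dd <- 2 + 2 * cos(2 * tt)
      ok <- dd > 1e-8 & abs(f) >= tol
      tt[ok] <- tt[ok] - f[ok] / dd[ok]
    }
    t[act] <- pmin(pmax(tt, -pi / 2), pi / 2)
  }
  t
}
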