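#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the standard
#' IUPAC sign convention: looking down the p2->p3 bond, the angle is
#' positive when the far bond (p3->p4) is rotated clockwise relative to
#' the near bond (p2->p1).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, coordinates in Angstrom.
#' @return Angle in degrees in the canonical range (-180, 180].
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("dihedral undefined: three consecutive points are collinear or coincident")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Wrap an angle (degrees) into (-180, 180].
.wrap180 <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180 & !is.na(y)] <- 180
  y
}

#' Minimal angular distance between two torsions
#'
#' Distance on the circle between two angles, optionally accounting for a
#' chemical 2-fold symmetry (terminal torsions whose two equivalent atom
#' namings differ by 180 degrees, e.g. chi2 of Asp/Phe/Tyr).
#'
#' @param a,b Angles in degrees (any representation; wrapped internally).
#' @param symmetry_order 1 (default) or 2.
#' @return Non-negative distance in degrees, at most 180 (90 for
#'   `symmetry_order = 2`).  `NA` propagates.
#' @export
angular_delta <- function(a, b, symmetry_order = 1L) {
  stopifnot(symmetry_order %in% c(1L, 2L))
  d <- abs(.wrap180(a - b))
  if (symmetry_order == 2L)
    d <- pmin(d, abs(.wrap180(a - b + 180)))
  d
}

#' Classify a peptide-bond omega torsion
#'
#' `trans` when within 30 degrees of planar trans (+/-180), `cis` when
#' within 30 degrees of planar cis (0), otherwise `twisted`.  The
#' boundary value of exactly 30 degrees is assigned to the non-twisted
#' (planar) class.
#'
#' @param omega Omega torsion(s) in degrees.
#' @param twist_cutoff Planarity tolerance in degrees (default 30).
#' @return Character vector: `"cis"`, `"trans"` or `"twisted"` (`NA` for
#'   undefined input).
#' @export
classify_omega <- function(omega, twist_cutoff = 30) {
  dev_cis <- abs(.wrap180(omega))
  dev_trans <- 180 - dev_cis
  out <- ifelse(dev_cis <= twist_cutoff, "cis",
                ifelse(dev_trans <= twist_cutoff, "trans", "twisted"))
  out[is.na(omega)] <- NA_character_
  out
}

# Place atom D from reference atoms using internal coordinates (NeRF).
# a, b, c: positions of the three reference atoms; the new atom is bonded
# to c with bond length `bond`, angle b-c-D `angle` (deg) and torsion
# a-b-c-D `torsion` (deg).  Consistent with dihedral(): measuring the
# built quadruple returns `torsion`.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  rot <- cbind(bc, m, n)
  c(rot %*% d2) + c
}
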