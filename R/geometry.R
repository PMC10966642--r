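# Vectorized geometric primitives shared by the codec, the loss, the
# stereochemistry module, the synthetic generator and the analysis suite.
# Coordinates are N x 3 matrices in nm; angles are radians.

.row_norms <- function(m) sqrt(rowSums(m * m))

.row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Bending angles at given atom triples
#'
#' Interior angle at the middle atom of each bonded 3-path, computed as the
#' arccos of the normalized dot product (clamped to `[-1, 1]`).  Two
#' collinear arms pointing the same way from the vertex give 0; opposed arms
#' give pi.  A zero-length arm yields `NaN` rather than a silent value.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param triples Integer matrix (m x 3) of atom indices `i, j, k`; the angle
#'   is measured at `j`.
#' @return Numeric vector of angles in radians, in `[0, pi]`.
#' @export
bending_angles <- function(coords, triples) {
  triples <- matrix(as.integer(triples), ncol = 3L)
  u <- coords[triples[, 1L], , drop = FALSE] - coords[triples[, 2L], , drop = FALSE]
  v <- coords[triples[, 3L], , drop = FALSE] - coords[triples[, 2L], , drop = FALSE]
  nu <- .row_norms(u); nv <- .row_norms(v)
  cosang <- rowSums(u * v) / (nu * nv)   # 0-length arm -> NaN, kept
  unname(acos(pmin(1, pmax(-1, cosang))))
}

#' Signed dihedral angles at given atom quadruples
#'
#' Torsion about the central bond `j-k` of each bonded 4-path, via the
#' two-plane normal construction with a full-quadrant arctangent; the result
#' lies in `(-pi, pi]` with the IUPAC sign convention (cis = 0, trans = pi).
#' Degenerate (collinear) central bonds yield `NaN`.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param quads Integer matrix (m x 4) of atom indices `i, j, k, l`.
#' @return Numeric vector of angles in radians in `(-pi, pi]`.
#' @export
dihedral_angles <- function(coords, quads) {
  quads <- matrix(as.integer(quads), ncol = 4L)
  b1 <- coords[quads[, 2L], , drop = FALSE] - coords[quads[, 1L], , drop = FALSE]
  b2 <- coords[quads[, 3L], , drop = FALSE] - coords[quads[, 2L], , drop = FALSE]
  b3 <- coords[quads[, 4L], , drop = FALSE] - coords[quads[, 3L], , drop = FALSE]
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  m1 <- .row_cross(n1, b2 / .row_norms(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  bad <- .row_norms(n1) < 1e-12 | .row_norms(n2) < 1e-12
  phi <- atan2(y, x)
  phi[phi <= -pi] <- pi
  phi[bad] <- NaN
  unname(phi)
}

#' Place an atom from internal coordinates
#'
#' Standard natural-extension (NeRF) construction: given three previously
#' placed reference atoms `a-b-c` and the internal coordinates of a new atom
#' `d` bonded to `c`, returns the Cartesian position such that
#' `|cd| = bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c Length-3 position vectors of the reference atoms.
#' @param bond Bond length c-d (nm).
#' @param angle Bending angle b-c-d (radians).
#' @param torsion Dihedral a-b-c-d (radians).
#' @return Length-3 position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
         ab[3L] * bc[1L] - ab[1L] * bc[3L],
         ab[1L] * bc[2L] - ab[2L] * bc[1L])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference frame: a, b, c are collinear")
  n <- n / nn
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), -sin(angle) * sin(torsion))
  unname(c + d2[1L] * bc + d2[2L] * m + d2[3L] * n)
}

#' Random proper rotation matrix
#'
#' Uniformly distributed 3 x 3 rotation (determinant +1), for invariance
#' tests and for orienting chains in the box.
#'
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# wrap an angle difference into (-pi, pi]
.wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- pi
  w
}
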