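# Small 3D geometry kernel shared by the grafting builder and the descriptor
# suite. All coordinates in Angstrom, all angles in degrees.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(v) sqrt(sum(v * v))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Signed torsion angle of four points
#'
#' IUPAC convention: cis = 0, sign from the right-hand rule about the central
#' bond, result in (-180, 180]. Uses the atan2 formulation, which is stable
#' near +-180 degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))  # -90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b1) < 1e-10 || .vnorm(b2) < 1e-10 || .vnorm(b3) < 1e-10) {
    stop("dihedral: consecutive points coincide")
  }
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-8 || .vnorm(n2) < 1e-8) {
    stop("dihedral: collinear bond vectors, torsion undefined")
  }
  u2 <- b2 / .vnorm(b2)
  ang <- .rad2deg(atan2(sum(.cross3(n1, n2) * u2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Bond angle p1-p2-p3 in degrees.
.bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  ct <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  .rad2deg(acos(max(-1, min(1, ct))))
}

# Natural-extension (NeRF) placement: position a new atom D given three placed
# atoms so that |C-D| = r, angle(B,C,D) = theta and torsion(A,B,C,D) = phi.
# ref1 = C (bonded), ref2 = B, ref3 = A.
.place_atom <- function(ref1, ref2, ref3, r, theta, phi) {
  th <- .deg2rad(theta); ph <- .deg2rad(phi)
  bc <- ref1 - ref2
  bc <- bc / .vnorm(bc)
  ab <- ref2 - ref3
  n <- .cross3(ab, bc)
  nn <- .vnorm(n)
  if (nn < 1e-8) stop("degenerate internal-coordinate reference frame (collinear)")
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  ref1 + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
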