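# Small 3-vector geometry kernel. Everything here is called from inner MC
# loops, so the functions stay allocation-light and unclassed.

vnorm3 <- function(v) sqrt(v[1L]^2 + v[2L]^2 + v[3L]^2)

unit3 <- function(v) {
  n <- sqrt(v[1L]^2 + v[2L]^2 + v[3L]^2)
  if (n < 1e-12) stop("cannot normalise a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp1 <- function(x) max(-1, min(1, x))

#' Bond angle at a vertex
#'
#' Angle in radians between the rays `vertex -> a` and `vertex -> b`.
#'
#' @param vertex,a,b Numeric 3-vectors (Angstrom).
#' @return Angle in radians in `[0, pi]`.
#' @export
angle_at <- function(vertex, a, b) {
  u <- unit3(a - vertex)
  v <- unit3(b - vertex)
  acos(clamp1(sum(u * v)))
}

#' Dihedral angle of four points
#'
#' Signed torsion `p1-p2-p3-p4` about the `p2-p3` axis, in radians in
#' `(-pi, pi]`, using the IUPAC sign convention (trans/anti = pi).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Dihedral angle in radians.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Rotate points about an axis
#'
#' Rodrigues rotation of one or more points about the axis through `origin`
#' with unit direction `axis`, by `theta` radians.
#'
#' @param pts Numeric 3-vector or n x 3 matrix.
#' @param origin Numeric 3-vector on the axis.
#' @param axis Unit 3-vector.
#' @param theta Rotation angle, radians.
#' @return Rotated points, same shape as `pts`.
#' @export
rotate_about_axis <- function(pts, origin, axis, theta) {
  ct <- cos(theta); st <- sin(theta)
  one_pt <- is.null(dim(pts))
  if (one_pt) pts <- matrix(pts, 1L, 3L)
  vx <- pts[, 1L] - origin[1L]
  vy <- pts[, 2L] - origin[2L]
  vz <- pts[, 3L] - origin[3L]
  av <- (vx * axis[1L] + vy * axis[2L] + vz * axis[3L]) * (1 - ct)
  out <- cbind(vx * ct + (axis[2L] * vz - axis[3L] * vy) * st + av * axis[1L] + origin[1L],
               vy * ct + (axis[3L] * vx - axis[1L] * vz) * st + av * axis[2L] + origin[2L],
               vz * ct + (axis[1L] * vy - axis[2L] * vx) * st + av * axis[3L] + origin[3L])
  if (one_pt) out[1L, ] else out
}

#' Place an atom from internal coordinates
#'
#' Standard z-matrix (NeRF) construction: returns the position `x` with
#' `|x - p| = len`, bond angle `x-p-r1 = theta` and dihedral
#' `x-p-r1-r2 = phi` (as measured by [dihedral()]).
#'
#' @param p Parent atom position (bonded to the new atom).
#' @param r1 Angle reference position.
#' @param r2 Dihedral reference position.
#' @param len Bond length, Angstrom.
#' @param theta Bond angle, radians.
#' @param phi Dihedral angle, radians.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(p, r1, r2, len, theta, phi) {
  u <- unit3(p - r1)
  w <- r2 - r1
  n <- cross3(w, u)
  nn <- vnorm3(n)
  if (nn < 1e-10) stop("dihedral reference is collinear with the bond axis", call. = FALSE)
  n <- n / nn
  m <- cross3(n, u)
  # local frame at p: u points from r1 to p
  d <- len * (-cos(theta) * u + sin(theta) * (-cos(phi) * m + sin(phi) * n))
  p + d
}

#' Measure internal coordinates of a placed atom
#'
#' Inverse of [place_atom()]: given `x` and the frame `(p, r1, r2)`, returns
#' the bond length, bond angle and dihedral that [place_atom()] would need to
#' reproduce `x`.
#'
#' @inheritParams place_atom
#' @param x Position to measure.
#' @return Numeric vector `c(len, theta, phi)`.
#' @export
measure_atom <- function(x, p, r1, r2) {
  c(vnorm3(x - p), angle_at(p, x, r1), dihedral(x, p, r1, r2))
}

# Minimum-image displacement matrix. `dx` is n x 3; `box` a scalar cubic edge
# or NULL; `periodic` a logical 3-vector saying which axes wrap.
min_image <- function(dx, box, periodic = c(TRUE, TRUE, FALSE)) {
  if (is.null(box)) return(dx)
  for (k in which(periodic)) {
    dx[, k] <- dx[, k] - box * round(dx[, k] / box)
  }
  dx
}
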