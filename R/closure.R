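# Chain closure geometry for the breakage/closure (CBC) move set under the
# constant-bond-length approximation.
#
# A displaced breakage atom leaves each bonded closure neighbor C with two
# distance constraints: |C - B'| = len to the moved atom and |C - A| = len to
# its outer anchor. The solution set of those two spheres is a circle; the
# closure must pick a point on it by a rule that is *exactly* reversible so
# the reverse-proximity criterion can hold to machine precision:
#
#  * default (lab_angle): the circle angle measured against a deterministic
#    lab reference is preserved - unique solution, regular at planar (trans)
#    geometry.
#  * alternative (anchor_angle, anchored closures only): the bond angle at
#    the anchor toward its fixed continuation A_next is preserved, cutting
#    the circle to two analytic solutions of which the nearer is taken;
#    degenerate at trans torsions.
#  * no anchor at all (terminal neighbor): the neighbor rides rigidly,
#    preserving its bond direction.

# circle of points P with |P - p1| = l1 and |P - p2| = l2
circle_geom <- function(p1, p2, l1, l2) {
  d <- p2 - p1
  dd <- vnorm3(d)
  if (dd < 1e-12) return(NULL)                       # coincident anchors
  if (dd > l1 + l2 - 1e-12 || dd < abs(l1 - l2) + 1e-12) return(NULL)
  dh <- d / dd
  x <- (dd * dd + l1 * l1 - l2 * l2) / (2 * dd)
  rho2 <- l1 * l1 - x * x
  if (rho2 <= 1e-14) return(NULL)
  # cache an orthonormal basis of the circle plane (deterministic lab ref)
  k <- which.min(abs(dh))
  e <- c(0, 0, 0); e[k] <- 1
  r1 <- e - (e[1L] * dh[1L] + e[2L] * dh[2L] + e[3L] * dh[3L]) * dh
  r1 <- r1 / sqrt(r1[1L]^2 + r1[2L]^2 + r1[3L]^2)
  r2 <- cross3(dh, r1)
  list(cen = p1 + x * dh, rho = sqrt(rho2), axis = dh, r1 = r1, r2 = r2)
}

# deterministic reference direction perpendicular to a unit axis
lab_reference <- function(axis) {
  k <- which.min(abs(axis))
  e <- c(0, 0, 0); e[k] <- 1
  unit3(e - sum(e * axis) * axis)
}

circle_angle_of <- function(p, g) {
  w <- p - g$cen
  atan2(sum(w * g$r2), sum(w * g$r1))
}

circle_point_at <- function(phi, g) {
  g$cen + g$rho * (cos(phi) * g$r1 + sin(phi) * g$r2)
}

#' Two-sphere closure with the proximity rule
#'
#' Returns the point `P` with `|P - anchor_a| = len_a` and
#' `|P - anchor_b| = len_b` nearest to `old_pos` on the solution circle.
#' Infeasible geometries (anchors farther apart than `len_a + len_b`, closer
#' than `|len_a - len_b|`, coincident anchors with unequal radii, or
#' `old_pos` on the circle axis so that the nearest point is not unique)
#' return `NULL`.
#'
#' @param anchor_a,anchor_b Fixed anchor positions (3-vectors).
#' @param len_a,len_b Required distances to the anchors, Angstrom (> 0).
#' @param old_pos Previous position used by the proximity rule.
#' @return A 3-vector satisfying both distances to 1e-10, or `NULL` if
#'   infeasible.
#' @export
solve_closure <- function(anchor_a, anchor_b, len_a, len_b, old_pos) {
  if (len_a <= 0 || len_b <= 0) stop("closure lengths must be > 0", call. = FALSE)
  g <- circle_geom(anchor_a, anchor_b, len_a, len_b)
  if (is.null(g)) return(NULL)
  w <- old_pos - g$cen
  w <- w - sum(w * g$axis) * g$axis
  nw <- vnorm3(w)
  if (nw < 1e-10) return(NULL)                       # on the axis: tie
  g$cen + g$rho * (w / nw)
}

# Case 1: preserve the bond angle at the anchor toward its continuation.
# Two analytic solutions; proximity picks the nearer. Returns position or NULL.
closure_anchor_angle <- function(b_new, a, a_next, len_cb, len_ca, c_old) {
  nh <- unit3(a_next - a)
  ub <- unit3(c_old - a)
  cth <- sum(ub * nh)
  sth <- sqrt(max(0, 1 - cth * cth))
  if (sth < 1e-8) return(NULL)                       # C on the A->A_next axis
  cen <- a + len_ca * cth * nh
  rad <- len_ca * sth
  e1 <- unit3(ub - cth * nh)
  e2 <- cross3(nh, e1)
  v <- cen - b_new
  c0 <- sum(v * v) + rad * rad
  c1 <- 2 * rad * sum(v * e1)
  c2 <- 2 * rad * sum(v * e2)
  Rr <- sqrt(c1 * c1 + c2 * c2)
  rhs <- len_cb * len_cb - c0
  if (Rr < 1e-12 || abs(rhs) > Rr) return(NULL)
  a0 <- atan2(c2, c1)
  da <- acos(clamp1(rhs / Rr))
  p1 <- cen + rad * (cos(a0 + da) * e1 + sin(a0 + da) * e2)
  p2 <- cen + rad * (cos(a0 - da) * e1 + sin(a0 - da) * e2)
  if (sum((p1 - c_old)^2) <= sum((p2 - c_old)^2)) p1 else p2
}

# Case 2: preserve the lab-referenced circle angle (terminal anchor).
closure_lab_angle <- function(b_new, b_old, a, len_cb, len_ca, c_old) {
  g_old <- circle_geom(b_old, a, len_cb, len_ca)
  g_new <- circle_geom(b_new, a, len_cb, len_ca)
  if (is.null(g_old) || is.null(g_new)) return(NULL)
  circle_point_at(circle_angle_of(c_old, g_old), g_new)
}

# ---- chart Jacobian factors ---------------------------------------------------
# J is the volume factor of the local free coordinate of the closure atom:
#   case 1: q = bond angle at the anchor;   J = len_ca / |w . (ua x ub)|
#   case 2: q = circle angle about the axis; J = rho / sin(gamma)
#   case 3: q = bond direction (solid angle); J = len^2 (constant)
# The acceptance uses J(new)/J(old); the closure map itself is the identity
# in these coordinates, so it contributes no extra factor.

closure_jac_case1 <- function(C, B, A, An) {
  ua <- unit3(C - B)
  ub <- unit3(C - A)
  nh <- unit3(An - A)
  cth <- sum(ub * nh)
  sth <- sqrt(max(0, 1 - cth * cth))
  if (sth < 1e-10) return(NA_real_)
  w <- (cth * ub - nh) / sth
  m <- abs(sum(w * cross3(ua, ub)))
  if (m < 1e-12) return(NA_real_)
  vnorm3(C - A) / m
}

closure_jac_case2 <- function(C, B, A) {
  g <- circle_geom(B, A, vnorm3(C - B), vnorm3(C - A))
  if (is.null(g)) return(NA_real_)
  gam <- angle_at(C, B, A)
  sg <- sin(gam)
  if (sg < 1e-12) return(NA_real_)
  g$rho / sg
}

# central finite-difference check of the same chart volume factors:
# J^-1 = |det d(q, l_a, l_b)/dC|, with q the case-specific free coordinate
fd_closure_jacobian <- function(C, B, A, An = NULL, case = c("anchor_angle", "lab_angle"),
                                h = 1e-6) {
  case <- match.arg(case)
  qfun <- if (case == "anchor_angle") {
    function(p) c(acos(clamp1(sum(unit3(p - A) * unit3(An - A)))), vnorm3(p - B), vnorm3(p - A))
  } else {
    function(p) {
      g <- circle_geom(B, A, vnorm3(p - B), vnorm3(p - A))
      c(circle_angle_of(p, g), vnorm3(p - B), vnorm3(p - A))
    }
  }
  M <- vapply(1:3, function(k) {
    dp <- c(0, 0, 0); dp[k] <- h
    (qfun(C + dp) - qfun(C - dp)) / (2 * h)
  }, numeric(3))
  1 / abs(det(M))
}
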