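# Move proposals and the Jacobian-corrected Metropolis acceptance rule.
#
# Every proposal returns an `mc_proposal`: trial coordinates for the moved
# atoms, the energy difference, the volume-element (Jacobian) ratio
# J(new)/J(old) of the sampled-plus-constrained local coordinates, the
# proposal-asymmetry (selection) ratio, and a feasibility flag. Infeasible
# proposals carry no trial coordinates and are always rejected, but count as
# attempts.

mc_proposal <- function(move_class, feasible = TRUE, moved = integer(0), trial = NULL,
                        delta_E = 0, jacobian_ratio = 1, selection_ratio = 1,
                        delta_V = 0, pv_term = 0, lnv_term = 0, extra = NULL) {
  structure(list(move_class = move_class, feasible = feasible, moved = moved,
                 trial = trial, delta_E = delta_E, jacobian_ratio = jacobian_ratio,
                 selection_ratio = selection_ratio, delta_V = delta_V,
                 pv_term = pv_term, lnv_term = lnv_term, extra = extra),
            class = "mc_proposal")
}

infeasible_proposal <- function(move_class) mc_proposal(move_class, feasible = FALSE)

# reposition external riders: keep each rider's internal coordinates
# (length, angle, dihedral w.r.t. its frame) while the frame moves
.apply_riders <- function(riders, Xold, Xnew_rows, moved) {
  if (!nrow(riders)) return(list(moved = moved, trial = Xnew_rows))
  lookup_new <- function(i) {
    w <- match(i, moved)
    if (is.na(w)) Xold[i, ] else Xnew_rows[w, ]
  }
  for (r in seq_len(nrow(riders))) {
    at <- riders$atom[r]; p <- riders$parent[r]; r1 <- riders$ref1[r]; r2 <- riders$ref2[r]
    ic <- measure_atom(Xold[at, ], Xold[p, ], Xold[r1, ], Xold[r2, ])
    newpos <- place_atom(lookup_new(p), lookup_new(r1), lookup_new(r2), ic[1L], ic[2L], ic[3L])
    moved <- c(moved, at)
    Xnew_rows <- rbind(Xnew_rows, newpos)
  }
  list(moved = moved, trial = Xnew_rows)
}

# finish a structural proposal: riders, delta energy
.finish_proposal <- function(cls, conf, entry, moved, trial, jac, sel, nlist, model) {
  rr <- .apply_riders(entry$riders, conf$coords, trial, moved)
  dE <- delta_energy_core(conf$coords, rr$trial, rr$moved, conf$box, conf$periodic, model,
                          nlist, cache = entry$cache)
  mc_proposal(cls, TRUE, rr$moved, rr$trial, delta_E = dE,
              jacobian_ratio = jac, selection_ratio = sel)
}

#' Propose a chain-breakage/closure move
#'
#' Displaces the breakage atom by a uniform random vector in a cube of
#' half-width `max_step`; every bonded closure neighbor is repositioned by
#' the reversible closure for its case (see closures in the package
#' overview); dependent external atoms ride with their frames. The
#' reverse-proximity criterion is verified: re-applying the exact reverse
#' displacement must recover the original closure positions to 1e-9
#' Angstrom, otherwise the proposal is infeasible.
#'
#' @param conf Current `mc_config`.
#' @param entry A compiled breakage entry from an `mc_moveplan`.
#' @param max_step Half-width of the displacement cube, Angstrom (defaults
#'   to the plan entry's step).
#' @param nlist Current neighbor list.
#' @param model Precompiled energy model.
#' @return An `mc_proposal`.
#' @export
propose_breakage_move <- function(conf, entry, max_step = entry$step, nlist, model) {
  X <- conf$coords
  b <- entry$atom
  d <- stats::runif(3L, -max_step, max_step)
  b_old <- X[b, ]
  b_new <- b_old + d
  ncl <- length(entry$closures)
  trial <- matrix(0, 1L + ncl, 3L)
  trial[1L, ] <- b_new
  moved <- c(b, entry$closure_atoms)
  jac <- 1
  for (k in seq_len(ncl)) {
    cl <- entry$closures[[k]]
    C_old <- X[cl$c, ]
    if (cl$case == "translate") {
      trial[k + 1L, ] <- C_old + d
      next
    }
    A <- X[cl$a, ]
    if (cl$case == "anchor_angle") {
      An <- X[cl$an, ]
      C_new <- closure_anchor_angle(b_new, A, An, cl$len_cb, cl$len_ca, C_old)
      if (is.null(C_new)) return(infeasible_proposal("breakage"))
      # reverse proximity: closing back from the trial state must recover C_old
      C_back <- closure_anchor_angle(b_old, A, An, cl$len_cb, cl$len_ca, C_new)
      if (is.null(C_back) || vnorm3(C_back - C_old) > 1e-9) return(infeasible_proposal("breakage"))
      j_old <- closure_jac_case1(C_old, b_old, A, An)
      j_new <- closure_jac_case1(C_new, b_new, A, An)
      if (is.na(j_old) || is.na(j_new)) return(infeasible_proposal("breakage"))
      jac <- jac * (j_new / j_old)
    } else {  # lab_angle
      g_old <- circle_geom(b_old, A, cl$len_cb, cl$len_ca)
      g_new <- circle_geom(b_new, A, cl$len_cb, cl$len_ca)
      if (is.null(g_old) || is.null(g_new)) return(infeasible_proposal("breakage"))
      phi <- circle_angle_of(C_old, g_old)
      C_new <- circle_point_at(phi, g_new)
      # exact reverse: the lab-referenced angle round-trips by construction;
      # verify to guard the reference-axis branch cut
      C_back <- circle_point_at(circle_angle_of(C_new, g_new), g_old)
      if (vnorm3(C_back - C_old) > 1e-9) return(infeasible_proposal("breakage"))
      sg_old <- sin(angle_at(C_old, b_old, A))
      sg_new <- sin(angle_at(C_new, b_new, A))
      if (sg_old < 1e-12 || sg_new < 1e-12) return(infeasible_proposal("breakage"))
      jac <- jac * (g_new$rho * sg_old) / (g_old$rho * sg_new)
    }
    trial[k + 1L, ] <- C_new
  }
  .finish_proposal("breakage", conf, entry, moved, trial, jac, 1, nlist, model)
}

#' Propose a crankshaft rotation
#'
#' Rotates the target atom about the axis through its two bonded flanking
#' atoms by a uniform angle in `[-max_angle, max_angle]`. Both adjacent bond
#' lengths are invariant by construction; the volume element of the rotation
#' coordinate is unchanged, so `jacobian_ratio = 1` and the proposal is
#' symmetric.
#'
#' @param conf Current `mc_config`.
#' @param entry Compiled crankshaft entry.
#' @param max_angle Maximum rotation, radians (defaults to the plan step).
#' @param nlist Current neighbor list.
#' @param model Precompiled energy model.
#' @return An `mc_proposal`.
#' @export
propose_crankshaft <- function(conf, entry, max_angle = entry$step, nlist, model) {
  X <- conf$coords
  f1 <- X[entry$flank[1L], ]
  f2 <- X[entry$flank[2L], ]
  ax <- f2 - f1
  nx <- vnorm3(ax)
  if (nx < 1e-10) stop("geometry error: crankshaft flanking atoms coincide", call. = FALSE)
  ax <- ax / nx
  th <- stats::runif(1L, -max_angle, max_angle)
  newpos <- rotate_about_axis(X[entry$atom, ], f1, ax, th)
  .finish_proposal("crankshaft", conf, entry, entry$atom, matrix(newpos, 1L, 3L),
                   1, 1, nlist, model)
}

#' Propose an internal-coordinate move
#'
#' Torsion entries rotate the dependent terminal subtree rigidly about the
#' bond axis (volume element unchanged, `jacobian_ratio = 1`). Bond-angle
#' entries rotate the subtree about an axis through the vertex perpendicular
#' to the angle plane and carry the volume-element factor
#' `sin(theta_new) / sin(theta_old)`; driving the angle to 0 or 180 degrees
#' is infeasible (the volume element vanishes).
#'
#' @param conf Current `mc_config`.
#' @param entry Compiled torsion or bond-angle entry.
#' @param max_step Maximum change, radians (defaults to the plan step).
#' @param nlist Current neighbor list.
#' @param model Precompiled energy model.
#' @return An `mc_proposal`.
#' @export
propose_internal <- function(conf, entry, max_step = entry$step, nlist, model) {
  X <- conf$coords
  d <- stats::runif(1L, -max_step, max_step)
  if (entry$class == "torsion") {
    a <- X[entry$axis[1L], ]
    b <- X[entry$axis[2L], ]
    ax <- b - a
    nx <- vnorm3(ax)
    if (nx < 1e-10) stop("geometry error: torsion axis atoms coincide", call. = FALSE)
    trial <- rotate_about_axis(X[entry$moved, , drop = FALSE], a, ax / nx, d)
    return(.finish_proposal("torsion", conf, entry, entry$moved, trial, 1, 1, nlist, model))
  }
  # bond angle
  i <- entry$triple[1L]; j <- entry$triple[2L]; k <- entry$triple[3L]
  vji <- X[i, ] - X[j, ]
  vjk <- X[k, ] - X[j, ]
  nvec <- cross3(vji, vjk)
  nn <- vnorm3(nvec)
  if (nn < 1e-10) {
    stop(sprintf("geometry error: angle %d-%d-%d is collinear; rotation plane undefined", i, j, k),
         call. = FALSE)
  }
  th_old <- angle_at(X[j, ], X[i, ], X[k, ])
  th_new <- th_old + d
  if (th_new <= 1e-6 || th_new >= pi - 1e-6) return(infeasible_proposal("bond_angle"))
  trial <- rotate_about_axis(X[entry$moved, , drop = FALSE], X[j, ], nvec / nn, d)
  .finish_proposal("bond_angle", conf, entry, entry$moved, trial,
                   sin(th_new) / sin(th_old), 1, nlist, model)
}

#' Jacobian ratio of a proposal
#'
#' Returns `J(new)/J(old)`, where `J` is the volume factor of the
#' transformation between the Cartesian coordinates of the moved fragment and
#' its sampled-plus-constrained local coordinates (the inverse determinant of
#' the matrix of partial derivatives of the local coordinates with respect to
#' the Cartesians). Analytic closed forms are used for every move class; the
#' finite-difference validator `fd_closure_jacobian` reproduces the closure
#' factors to 1e-6 relative (exercised in the test suite).
#'
#' @param proposal An `mc_proposal`.
#' @param conf,topology Unused; kept for call-site symmetry.
#' @return Dimensionless scalar > 0 for feasible proposals.
#' @export
jacobian_ratio <- function(proposal, conf = NULL, topology = NULL) {
  if (!proposal$feasible) stop("jacobian_ratio: proposal is infeasible", call. = FALSE)
  proposal$jacobian_ratio
}

#' Propose an isotropic NPT volume move
#'
#' Samples a uniform step in `ln V`, scales the cubic box edge isotropically
#' and moves each molecule rigidly so that its center of mass scales
#' affinely; intramolecular geometry (all bond lengths) is untouched. The
#' enthalpy used in the acceptance is
#' `dE + P dV - n_molecules kT ln(V_new/V_old)` (the center-of-mass scaling
#' convention: sampling in ln V makes the ideal-gas stationary density
#' proportional to V^(n-1) exp(-beta P V), so <V> = n kT / P).
#'
#' @param conf Current `mc_config` (must have a box).
#' @param max_dlnV Maximum |d ln V| per attempt.
#' @param n_molecules Number of molecules whose centers of mass scale.
#' @param pressure Pressure, atm.
#' @param temperature Temperature, K.
#' @param topology An `mc_topology` (for masses and molecule membership).
#' @param nlist Current neighbor list.
#' @param model Precompiled energy model.
#' @return An `mc_proposal` with `delta_V`, the `P dV` term and the
#'   `-n kT ln(V'/V)` term stored for the acceptance rule.
#' @export
propose_volume_move <- function(conf, max_dlnV, n_molecules, pressure, temperature,
                                topology, nlist, model) {
  if (is.null(conf$box)) stop("volume move requires a periodic box", call. = FALSE)
  dln <- stats::runif(1L, -max_dlnV, max_dlnV)
  V_old <- conf$box^3
  V_new <- V_old * exp(dln)
  L_new <- V_new^(1 / 3)
  if (is.finite(nlist$cutoff) && L_new < 2 * nlist$cutoff) {
    warning("volume move rejected: proposed box smaller than twice the cutoff", call. = FALSE)
    return(infeasible_proposal("volume"))
  }
  f <- L_new / conf$box
  X <- conf$coords
  masses <- topology$atoms$mass
  com <- rowsum(X * masses, topology$mol) / as.numeric(rowsum(matrix(masses), topology$mol))
  trial <- X + (f - 1) * com[topology$mol, , drop = FALSE]
  dimnames(trial) <- NULL
  # energy difference: intramolecular terms are rigid, only intermolecular
  # nonbonded pairs change; recompute both pair sets under old and new boxes
  inter_pairs <- function(P, is14) {
    if (!nrow(P)) return(cbind(P, is14 = logical(0)))
    keep <- topology$mol[P[, 1L]] != topology$mol[P[, 2L]]
    cbind(P[keep, , drop = FALSE], is14 = is14[keep])
  }
  pi1 <- inter_pairs(nlist$pairs_inner, nlist$is14_inner)
  pi2 <- inter_pairs(nlist$pairs_shell, nlist$is14_shell)
  I <- c(pi1[, 1L], pi2[, 1L]); J <- c(pi1[, 2L], pi2[, 2L])
  f14 <- as.logical(c(pi1[, 3L], pi2[, 3L]))
  e_old <- nb_energy_pairs(I, J, f14, X, conf$box, conf$periodic, model, nlist$cutoff)
  e_new <- nb_energy_pairs(I, J, f14, trial, L_new, conf$periodic, model, nlist$cutoff)
  dV <- V_new - V_old
  kT <- mc_constants$kB * temperature
  mc_proposal("volume", TRUE, moved = seq_len(nrow(X)), trial = trial,
              delta_E = e_new - e_old,
              delta_V = dV,
              pv_term = pressure * dV * mc_constants$atm_A3,
              lnv_term = -n_molecules * kT * log(V_new / V_old),
              extra = list(box_new = L_new))
}

#' Metropolis acceptance with Jacobian correction
#'
#' Accepts with probability
#' `min(1, selection_ratio * exp(-beta dH) * jacobian_ratio)`, where
#' `dH = dE + P dV - n kT ln(V'/V)` for volume moves and `dH = dE`
#' otherwise. Infeasible proposals are always rejected (they still count as
#' attempts at the call site); a non-finite `dE` rejects with a warning.
#'
#' @param proposal An `mc_proposal`.
#' @param temperature Temperature, K.
#' @return `TRUE` if accepted.
#' @export
metropolis_accept <- function(proposal, temperature) {
  if (!proposal$feasible) return(FALSE)
  if (!is.finite(proposal$delta_E)) {
    warning("rejecting proposal with non-finite energy difference", call. = FALSE)
    return(FALSE)
  }
  beta <- 1 / (mc_constants$kB * temperature)
  dH <- proposal$delta_E + proposal$pv_term + proposal$lnv_term
  p <- proposal$selection_ratio * exp(-beta * dH) * proposal$jacobian_ratio
  if (p >= 1) TRUE else stats::runif(1L) < p
}
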