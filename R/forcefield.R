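# Configuration energies: 6-12 Lennard-Jones, Coulomb with a sigmoidal
# distance-dependent dielectric (implicit solvent), harmonic bond-angle and
# Fourier torsion terms, Ryckaert-Bellemans cosine polynomials for the acyl
# chains. No bond-stretch term: bond lengths are held fixed (CBLA).

#' Dielectric screening parameters
#'
#' @param plateau_d Plateau value of the dielectric permittivity (bulk
#'   water ~ 78). Must be >= 1.
#' @param slope_s Slope of the sigmoidal rise, 1/Angstrom. Must be > 0.
#' @return A list of class `mc_dielectric`.
#' @export
dielectric_params <- function(plateau_d = 78, slope_s = 0.654) {
  if (plateau_d < 1) stop("plateau_d must be >= 1", call. = FALSE)
  if (slope_s <= 0) stop("slope_s must be > 0", call. = FALSE)
  structure(list(plateau_d = plateau_d, slope_s = slope_s), class = "mc_dielectric")
}

#' Sigmoidal distance-dependent dielectric
#'
#' \deqn{\epsilon(r) = d - \frac{d-1}{2}\,\big((sr)^2 + 2sr + 2\big)\,e^{-sr}}
#'
#' The polynomial and exponential take the product `s * r` as argument; with
#' this convention `eps(10; d = 78, s = 0.65) = 74.69` and
#' `eps(10; d = 78, s = 0.15) = 15.72`. The function rises monotonically from
#' `eps(0) = 1` to the plateau `d`, modelling the loss of water screening
#' close to the solute surface.
#'
#' @param r Distance(s), Angstrom. Must be >= 0.
#' @param params An `mc_dielectric` from [dielectric_params()].
#' @return Dielectric value(s), dimensionless, in `[1, plateau_d]`.
#' @export
dielectric <- function(r, params = dielectric_params()) {
  if (any(r < 0)) stop("dielectric: r must be >= 0", call. = FALSE)
  d <- params$plateau_d
  s <- params$slope_s
  x <- s * r
  d - (d - 1) / 2 * (x^2 + 2 * x + 2) * exp(-x)
}

# ---- energy model compilation ------------------------------------------------

# Precompute everything the inner loops need: per-atom LJ/charge vectors,
# 1-2/1-3 exclusions and 1-4 scaling sets (graph distances over the full bond
# tree), vectorised bonded-term tables and per-atom term indices.
energy_model <- function(topology, dielectric = NULL, dielectric_mode = c("pair", "constant", "interface")) {
  p <- topology$params
  dielectric_mode <- match.arg(dielectric_mode)
  n <- topology$n_atoms
  ljmap <- stats::setNames(seq_len(nrow(p$lj)), p$lj$type)
  ti <- ljmap[p$atoms$type]
  if (any(is.na(ti))) {
    stop("forcefield error: atom type(s) without LJ parameters: ",
         paste(unique(p$atoms$type[is.na(ti)]), collapse = ", "), call. = FALSE)
  }
  rmin <- p$lj$rmin_half[ti]
  eps <- p$lj$epsilon[ti]
  q <- p$atoms$charge

  # graph-distance 1..3 sets from the full adjacency (externals included)
  adj <- topology$adj
  excl <- vector("list", n)   # distance 1 or 2
  s14 <- vector("list", n)    # distance exactly 3
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    # [i] <- list(...) keeps empty entries (a [[i]] <- NULL would drop them)
    excl[i] <- list(as.integer(sort(c(d1, d2))))
    s14[i] <- list(as.integer(sort(d3)))
  }

  def <- p$defaults
  getdef <- function(nm, fallback) if (!is.null(def[[nm]])) def[[nm]] else fallback
  diel <- if (is.null(dielectric)) {
    dielectric_params(getdef("dielectric_d", 78), getdef("dielectric_s", 0.654))
  } else dielectric

  by_atom <- function(idx_mat) {
    out <- vector("list", n)
    if (is.null(idx_mat) || !nrow(idx_mat)) return(out)
    for (r in seq_len(nrow(idx_mat))) {
      for (a in unique(idx_mat[r, ])) out[[a]] <- c(out[[a]], r)
    }
    out
  }

  ang <- as.matrix(p$angles[, c("i", "j", "k")])
  storage.mode(ang) <- "integer"
  tor <- as.matrix(p$torsions[, c("i", "j", "k", "l")])
  storage.mode(tor) <- "integer"
  rbm <- as.matrix(p$rb[, c("i", "j", "k", "l")])
  storage.mode(rbm) <- "integer"

  list(
    n = n,
    rmin = rmin, eps = eps, q = q,
    has_lj = any(eps != 0), has_q = any(q != 0),
    excl = excl, s14 = s14,
    lj14 = getdef("lj14_scale", 0.5),
    coul14 = getdef("coul14_scale", 1 / 1.2),
    kqq = getdef("coulomb_constant", mc_constants$coulomb),
    diel = diel, diel_mode = dielectric_mode,
    ang = ang, ang_k = p$angles$k_theta, ang_th0 = p$angles$theta0,
    tor = tor, tor_v = p$torsions$v, tor_n = p$torsions$n, tor_g = p$torsions$gamma,
    rb = rbm, rb_c = if (nrow(p$rb)) as.matrix(p$rb[, c("c0", "c1", "c2", "c3", "c4", "c5")]) else matrix(0, 0, 6),
    ang_by_atom = by_atom(ang), tor_by_atom = by_atom(tor), rb_by_atom = by_atom(rbm)
  )
}

# effective dielectric for pair distances r (vector); midz only used in
# interface mode (|z| of the pair midpoint relative to the bilayer midplane)
.eff_dielectric <- function(r, model, midz = NULL) {
  switch(model$diel_mode,
    constant = rep(1, length(r)),
    pair = dielectric(r, model$diel),
    interface = dielectric(abs(midz), model$diel)
  )
}

# nonbonded energy of explicit pair vectors I, J with 1-4 flags
nb_energy_pairs <- function(I, J, is14, X, box, periodic, model, cutoff,
                            overlap_error = FALSE) {
  if (!length(I)) return(0)
  if (!model$has_lj && !model$has_q && !overlap_error) return(0)
  dxx <- X[I, 1L] - X[J, 1L]
  dxy <- X[I, 2L] - X[J, 2L]
  dxz <- X[I, 3L] - X[J, 3L]
  if (!is.null(box)) {
    if (periodic[1L]) dxx <- dxx - box * round(dxx / box)
    if (periodic[2L]) dxy <- dxy - box * round(dxy / box)
    if (periodic[3L]) dxz <- dxz - box * round(dxz / box)
  }
  r2 <- dxx * dxx + dxy * dxy + dxz * dxz
  if (overlap_error && any(r2 < 0.01)) {
    w <- which.min(r2)
    stop(sprintf("overlap error: atoms %d and %d are %.4f Angstrom apart", I[w], J[w], sqrt(r2[w])),
         call. = FALSE)
  }
  keep <- r2 < cutoff^2
  if (!any(keep)) return(0)
  I <- I[keep]; J <- J[keep]; is14 <- is14[keep]; r2 <- r2[keep]
  e <- 0
  if (model$has_lj) {
    rm <- model$rmin[I] + model$rmin[J]
    ee <- sqrt(model$eps[I] * model$eps[J])
    s6 <- (rm * rm / r2)^3
    e <- sum((1 + is14 * (model$lj14 - 1)) * ee * (s6 * s6 - 2 * s6))
  }
  if (model$has_q) {
    r <- sqrt(r2)
    midz <- if (model$diel_mode == "interface") (X[I, 3] + X[J, 3]) / 2 else NULL
    ec <- model$kqq * model$q[I] * model$q[J] / (.eff_dielectric(r, model, midz) * r)
    e <- e + sum((1 + is14 * (model$coul14 - 1)) * ec)
  }
  e
}

# nonbonded energy of atom i against candidate partners js (exclusions
# removed, 1-4 detected here); used on the delta path
nb_energy_atom <- function(i, js, X, box, periodic, model, cutoff) {
  if (!length(js)) return(0)
  js <- js[!(js %in% model$excl[[i]]) & js != i]
  if (!length(js)) return(0)
  is14 <- js %in% model$s14[[i]]
  nb_energy_pairs(rep.int(i, length(js)), js, is14, X, box, periodic, model, cutoff)
}

# ---- neighbor list -----------------------------------------------------------

#' Build a Verlet-style neighbor list
#'
#' Pairs within `cutoff` are classified as inner; pairs in
#' `(cutoff, cutoff + shell]` as shell. Energies are evaluated over the union
#' with plain truncation at `cutoff` by current distance, so the shell
#' guarantees that the list stays valid between rebuilds. 1-2 and 1-3 bonded
#' pairs are excluded; 1-4 pairs are kept and flagged for scaling.
#'
#' @param conf An `mc_config`.
#' @param topology An `mc_topology`.
#' @param cutoff Interaction cutoff, Angstrom.
#' @param shell Shell width beyond the cutoff, Angstrom.
#' @param model Optional precompiled energy model (internal use).
#' @return An object of class `mc_nlist` with `pairs_inner`, `pairs_shell`
#'   (2-column index matrices), `is14_inner`/`is14_shell` flags, a combined
#'   per-atom adjacency `adj`, and `age = 0`.
#' @export
build_neighbor_list <- function(conf, topology, cutoff = 10, shell = 10, model = NULL) {
  if (is.null(model)) model <- energy_model(topology)
  X <- conf$coords
  n <- nrow(X)
  box <- conf$box
  if (!is.null(box) && box < 2 * (cutoff + shell) && any(conf$periodic)) {
    warning(sprintf("box edge %.1f < 2 * (cutoff + shell) = %.1f: minimum image sees at most one image per pair",
                    box, 2 * (cutoff + shell)), call. = FALSE)
  }
  rmax2 <- if (is.finite(cutoff)) (cutoff + shell)^2 else Inf
  Ilist <- vector("list", n); Jlist <- vector("list", n); Rlist <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    dx <- X[js, , drop = FALSE] - matrix(X[i, ], length(js), 3L, byrow = TRUE)
    dx <- min_image(dx, box, conf$periodic)
    r2 <- rowSums(dx * dx)
    keep <- r2 <= rmax2
    js <- js[keep]
    if (!length(js)) next
    js_ok <- !(js %in% model$excl[[i]])
    js <- js[js_ok]
    if (!length(js)) next
    Ilist[[i]] <- rep.int(i, length(js))
    Jlist[[i]] <- js
    Rlist[[i]] <- r2[keep][js_ok]
  }
  I <- unlist(Ilist); J <- unlist(Jlist); r2 <- unlist(Rlist)
  if (is.null(I)) { I <- integer(0); J <- integer(0); r2 <- numeric(0) }
  inner <- if (is.finite(cutoff)) r2 <= cutoff^2 else rep(TRUE, length(r2))
  is14 <- mapply(function(i, j) j %in% model$s14[[i]], I, J)
  if (!length(I)) is14 <- logical(0)
  adj <- vector("list", n)
  if (length(I)) {
    for (k in seq_along(I)) {
      adj[[I[k]]] <- c(adj[[I[k]]], J[k])
      adj[[J[k]]] <- c(adj[[J[k]]], I[k])
    }
  }
  structure(list(
    pairs_inner = cbind(i = I[inner], j = J[inner]),
    pairs_shell = cbind(i = I[!inner], j = J[!inner]),
    is14_inner = is14[inner], is14_shell = is14[!inner],
    adj = adj, age = 0L, cutoff = cutoff, shell = shell
  ), class = "mc_nlist")
}

#' Total nonbonded energy
#'
#' Sum of Lennard-Jones and screened-Coulomb pair energies over the neighbor
#' list (inner and shell pairs), truncated at the cutoff by current
#' minimum-image distance. 1-2/1-3 pairs are excluded, 1-4 pairs scaled by
#' the parameter-file factors.
#'
#' @param conf An `mc_config`.
#' @param nlist An `mc_nlist` from [build_neighbor_list()], current for
#'   `conf` within its shell guarantee.
#' @param topology An `mc_topology`.
#' @param model Optional precompiled energy model.
#' @return Energy in kcal/mol.
#' @export
nonbonded_energy <- function(conf, nlist, topology, model = NULL) {
  if (is.null(model)) model <- energy_model(topology)
  X <- conf$coords
  e <- nb_energy_pairs(nlist$pairs_inner[, 1L], nlist$pairs_inner[, 2L], nlist$is14_inner,
                       X, conf$box, conf$periodic, model, nlist$cutoff, overlap_error = TRUE)
  if (nrow(nlist$pairs_shell)) {
    e <- e + nb_energy_pairs(nlist$pairs_shell[, 1L], nlist$pairs_shell[, 2L], nlist$is14_shell,
                             X, conf$box, conf$periodic, model, nlist$cutoff, overlap_error = TRUE)
  }
  e
}

# ---- bonded terms ------------------------------------------------------------

# vectorised bond angles for an index matrix (i, j, k); j is the vertex
.angles_of <- function(X, idx) {
  ax <- X[idx[, 1L], 1L] - X[idx[, 2L], 1L]
  ay <- X[idx[, 1L], 2L] - X[idx[, 2L], 2L]
  az <- X[idx[, 1L], 3L] - X[idx[, 2L], 3L]
  bx <- X[idx[, 3L], 1L] - X[idx[, 2L], 1L]
  by <- X[idx[, 3L], 2L] - X[idx[, 2L], 2L]
  bz <- X[idx[, 3L], 3L] - X[idx[, 2L], 3L]
  na <- sqrt(ax^2 + ay^2 + az^2); nb <- sqrt(bx^2 + by^2 + bz^2)
  if (any(na < 1e-10) || any(nb < 1e-10)) {
    w <- which(na < 1e-10 | nb < 1e-10)[1L]
    stop(sprintf("geometry error: angle %d-%d-%d undefined (coincident atoms)",
                 idx[w, 1L], idx[w, 2L], idx[w, 3L]), call. = FALSE)
  }
  cth <- (ax * bx + ay * by + az * bz) / (na * nb)
  acos(pmin(1, pmax(-1, cth)))
}

# vectorised dihedrals for an index matrix (i, j, k, l); column arithmetic
# (no intermediate cbind) because this sits on the per-move hot path
.dihedrals_of <- function(X, idx) {
  b1x <- X[idx[, 2L], 1L] - X[idx[, 1L], 1L]
  b1y <- X[idx[, 2L], 2L] - X[idx[, 1L], 2L]
  b1z <- X[idx[, 2L], 3L] - X[idx[, 1L], 3L]
  b2x <- X[idx[, 3L], 1L] - X[idx[, 2L], 1L]
  b2y <- X[idx[, 3L], 2L] - X[idx[, 2L], 2L]
  b2z <- X[idx[, 3L], 3L] - X[idx[, 2L], 3L]
  b3x <- X[idx[, 4L], 1L] - X[idx[, 3L], 1L]
  b3y <- X[idx[, 4L], 2L] - X[idx[, 3L], 2L]
  b3z <- X[idx[, 4L], 3L] - X[idx[, 3L], 3L]
  n1x <- b1y * b2z - b1z * b2y; n1y <- b1z * b2x - b1x * b2z; n1z <- b1x * b2y - b1y * b2x
  n2x <- b2y * b3z - b2z * b3y; n2y <- b2z * b3x - b2x * b3z; n2z <- b2x * b3y - b2y * b3x
  nb2 <- sqrt(b2x^2 + b2y^2 + b2z^2)
  if (any(nb2 < 1e-10)) stop("geometry error: zero-length central bond in a torsion", call. = FALSE)
  ux <- b2x / nb2; uy <- b2y / nb2; uz <- b2z / nb2
  m1x <- n1y * uz - n1z * uy; m1y <- n1z * ux - n1x * uz; m1z <- n1x * uy - n1y * ux
  atan2(m1x * n2x + m1y * n2y + m1z * n2z, n1x * n2x + n1y * n2y + n1z * n2z)
}

# bonded energy restricted to given term indices (NULL = all)
.bonded_terms_energy <- function(X, model, ang_idx = NULL, tor_idx = NULL, rb_idx = NULL) {
  e <- 0
  ai <- if (is.null(ang_idx)) seq_len(nrow(model$ang)) else ang_idx
  if (length(ai)) {
    th <- .angles_of(X, model$ang[ai, , drop = FALSE])
    e <- e + sum(model$ang_k[ai] * (th - model$ang_th0[ai])^2)
  }
  ti <- if (is.null(tor_idx)) seq_len(nrow(model$tor)) else tor_idx
  if (length(ti)) {
    ph <- .dihedrals_of(X, model$tor[ti, , drop = FALSE])
    e <- e + sum(model$tor_v[ti] / 2 * (1 + cos(model$tor_n[ti] * ph - model$tor_g[ti])))
  }
  ri <- if (is.null(rb_idx)) seq_len(nrow(model$rb)) else rb_idx
  if (length(ri)) {
    ph <- .dihedrals_of(X, model$rb[ri, , drop = FALSE])
    cpsi <- -cos(ph)   # RB convention: psi = phi - pi, trans (phi = pi) -> psi = 0
    cp <- cbind(1, cpsi, cpsi^2, cpsi^3, cpsi^4, cpsi^5)
    e <- e + sum(cp * model$rb_c[ri, , drop = FALSE])
  }
  e
}

#' Total bonded energy
#'
#' Harmonic bond-angle terms, Fourier torsion terms `V/2 (1 + cos(n phi -
#' gamma))`, and Ryckaert-Bellemans cosine polynomials
#' `sum_k c_k cos(psi)^k` with `psi = phi - 180` (trans = 0) for the acyl
#' chain torsions. There is no bond-stretch term: bond lengths are fixed.
#'
#' @param conf An `mc_config`.
#' @param topology An `mc_topology`.
#' @param model Optional precompiled energy model.
#' @return Energy in kcal/mol.
#' @export
bonded_energy <- function(conf, topology, model = NULL) {
  if (is.null(model)) model <- energy_model(topology)
  .bonded_terms_energy(conf$coords, model)
}

#' Total potential energy (bonded + nonbonded)
#'
#' @inheritParams nonbonded_energy
#' @return Energy in kcal/mol.
#' @export
total_energy <- function(conf, nlist, topology, model = NULL) {
  if (is.null(model)) model <- energy_model(topology)
  bonded_energy(conf, topology, model) + nonbonded_energy(conf, nlist, topology, model)
}

# per-moved-set cache: bonded term indices touching the set and the
# non-excluded pairs within the set (fixed for a given move plan entry)
build_delta_cache <- function(moved, model) {
  wI <- integer(0); wJ <- integer(0); w14 <- logical(0)
  m <- length(moved)
  if (m > 1L) {
    for (a in seq_len(m - 1L)) {
      i <- moved[a]
      js <- moved[(a + 1L):m]
      js <- js[!(js %in% model$excl[[i]])]
      if (length(js)) {
        wI <- c(wI, rep.int(i, length(js)))
        wJ <- c(wJ, js)
        w14 <- c(w14, js %in% model$s14[[i]])
      }
    }
  }
  list(moved = moved,
       ai = unique(unlist(model$ang_by_atom[moved])) %||% integer(0),
       ti = unique(unlist(model$tor_by_atom[moved])) %||% integer(0),
       ri = unique(unlist(model$rb_by_atom[moved])) %||% integer(0),
       wI = wI, wJ = wJ, w14 = w14)
}

# core of delta_energy used by the sampler: `Xold` full matrix, `trial` an
# m x 3 matrix for `moved` atom ids; neighbor candidates from nlist$adj
delta_energy_core <- function(Xold, trial, moved, box, periodic, model, nlist, cache = NULL) {
  if (is.null(cache)) cache <- build_delta_cache(moved, model)
  cutoff <- nlist$cutoff
  Xnew <- Xold
  Xnew[moved, ] <- trial
  e_b_old <- .bonded_terms_energy(Xold, model, cache$ai, cache$ti, cache$ri)
  e_b_new <- .bonded_terms_energy(Xnew, model, cache$ai, cache$ti, cache$ri)
  if (!model$has_lj && !model$has_q) return(e_b_new - e_b_old)
  # nonbonded: moved vs static partners (from the pair list) + within-set pairs
  I <- cache$wI; J <- cache$wJ; f14 <- cache$w14
  for (i in moved) {
    js <- nlist$adj[[i]]
    if (!length(js)) next
    js <- js[!(js %in% moved)]
    if (!length(js)) next
    I <- c(I, rep.int(i, length(js)))
    J <- c(J, js)
    f14 <- c(f14, js %in% model$s14[[i]])
  }
  e_nb_old <- nb_energy_pairs(I, J, f14, Xold, box, periodic, model, cutoff)
  e_nb_new <- nb_energy_pairs(I, J, f14, Xnew, box, periodic, model, cutoff)
  (e_b_new + e_nb_new) - (e_b_old + e_nb_old)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Energy difference of a local move
#'
#' Returns `E(trial) - E(current)` restricted to terms involving the moved
#' atoms; equal to the full-recompute difference because all untouched terms
#' cancel.
#'
#' @param conf Current `mc_config`.
#' @param trial_coords m x 3 matrix of trial coordinates for `moved_atoms`.
#' @param moved_atoms Integer ids of atoms whose coordinates differ.
#' @param nlist Neighbor list current for `conf`.
#' @param topology An `mc_topology`.
#' @param model Optional precompiled energy model.
#' @return Energy difference, kcal/mol.
#' @export
delta_energy <- function(conf, trial_coords, moved_atoms, nlist, topology, model = NULL) {
  if (is.null(model)) model <- energy_model(topology)
  trial_coords <- matrix(trial_coords, length(moved_atoms), 3L)
  still <- rowSums(abs(trial_coords - conf$coords[moved_atoms, , drop = FALSE])) == 0
  other <- setdiff(seq_len(nrow(conf$coords)), moved_atoms)
  # contract check: nothing outside moved_atoms may differ (trivially true
  # here since only moved rows are supplied), and moved rows should differ
  # unless the proposal is a no-op
  if (length(moved_atoms) == 0L) {
    stop("contract error: moved_atoms is empty", call. = FALSE)
  }
  delta_energy_core(conf$coords, trial_coords, moved_atoms, conf$box, conf$periodic, model, nlist)
}
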