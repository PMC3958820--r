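# Trajectory observables: energy-histogram Gaussian fit and fluctuation heat
# capacity, mass-weighted covariance and Schlitter entropy, torsion
# distributions, electron density profile and head-to-head distance, P-N
# vector orientation, area per lipid and area compressibility, and
# center-of-mass mean square displacement.

#' Fit a Gaussian to an energy histogram
#'
#' Histograms the series after discarding `burn_in` cycles and fits
#' `A * exp(-(E - mean)^2 / (2 sd^2))` to the bin counts by nonlinear least
#' squares.
#'
#' @param series Numeric energy (or enthalpy) series, kcal/mol.
#' @param burn_in Number of leading values to discard.
#' @param bins Number of histogram bins.
#' @return A list of class `mc_histfit`: `mean`, `sd`, `amplitude`,
#'   `bin_edges`, `counts`, `residual` (RMS of fit residuals).
#' @export
fit_energy_histogram <- function(series, burn_in = 0, bins = 60) {
  x <- series[(burn_in + 1):length(series)]
  if (length(x) < 10) stop("fit error: too few values after burn-in", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("fit error: degenerate (constant) energy series", call. = FALSE)
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  st <- list(A = max(counts), m = mean(x), s = stats::sd(x))
  fit <- minpack.lm::nlsLM(counts ~ A * exp(-(mids - m)^2 / (2 * s^2)),
                           start = st,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(mean = unname(cf["m"]), sd = abs(unname(cf["s"])),
                 amplitude = unname(cf["A"]), bin_edges = h$breaks, counts = counts,
                 residual = sqrt(mean(stats::resid(fit)^2))),
            class = "mc_histfit")
}

#' Fluctuation heat capacity
#'
#' `c = sigma^2 / (k_B T^2)` from the fitted standard deviation of the
#' energy (canonical ensemble) or enthalpy (isobaric ensemble) histogram.
#'
#' @param fit An `mc_histfit` (or any list with an `sd` element, kcal/mol).
#' @param temperature Temperature, K.
#' @return Heat capacity, kcal/(mol K).
#' @export
heat_capacity <- function(fit, temperature) {
  fit$sd^2 / (mc_constants$kB * temperature^2)
}

#' Coordinate covariance matrix of a trajectory
#'
#' Covariance of the flattened Cartesian coordinates (x1, y1, z1, x2, ...)
#' over the selected frames: `sigma_ij = <(x_i - <x_i>)(x_j - <x_j>)>`.
#' No roto-translational superposition is applied by default (set
#' `superpose = TRUE` to remove the center of mass first).
#'
#' @param trajectory An `mc_trajectory`.
#' @param atom_selection Integer atom ids (default: all atoms).
#' @param window Integer frame indices to use (default: all saved frames).
#' @param superpose Remove the per-frame mass-weighted center of mass.
#' @return A `3m x 3m` covariance matrix, Angstrom^2.
#' @export
covariance_matrix <- function(trajectory, atom_selection = NULL, window = NULL,
                              superpose = FALSE) {
  frames <- trajectory$frames
  if (is.null(window)) window <- seq_along(frames)
  if (length(window) < 2) stop("covariance needs at least 2 frames", call. = FALSE)
  if (is.null(atom_selection)) atom_selection <- seq_len(trajectory$topology$n_atoms)
  masses <- trajectory$topology$atoms$mass[atom_selection]
  mat <- t(vapply(window, function(w) {
    X <- frames[[w]]$coords[atom_selection, , drop = FALSE]
    if (superpose) X <- sweep(X, 2L, colSums(X * masses) / sum(masses))
    as.numeric(t(X))
  }, numeric(3 * length(atom_selection))))
  C <- stats::cov(mat)
  (C + t(C)) / 2
}

#' Schlitter configurational entropy
#'
#' Upper-bound entropy from the mass-weighted coordinate covariance:
#' \deqn{S = \frac{k_B}{2} \ln\det\big(1 + \frac{k_B T e^2}{\hbar^2}
#'   M^{1/2} C M^{1/2}\big)}
#' with `e` Euler's number and `M` the diagonal matrix of atomic masses
#' (each mass repeated for x, y, z). In one dimension this reduces to
#' `S = (k_B/2) ln(1 + k_B T e^2 m sigma^2 / hbar^2)`.
#'
#' @param covariance `3m x 3m` covariance matrix, Angstrom^2.
#' @param masses Atomic masses, amu (length m; expanded x3 internally).
#' @param temperature Temperature, K.
#' @return A list of class `mc_entropy`: `entropy` (kcal/(mol K)),
#'   `log_det`, `n_dof`.
#' @export
schlitter_entropy <- function(covariance, masses, temperature) {
  n <- nrow(covariance)
  if (length(masses) * 3L == n) masses <- rep(masses, each = 3L)
  if (length(masses) != n) stop("masses do not match the covariance dimension", call. = FALSE)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  cst <- mc_constants
  # dimensionless prefactor: kB T e^2 m sigma^2 / hbar^2 with SI conversion
  pref <- cst$kB_J * temperature * cst$euler^2 * cst$amu_kg * 1e-20 / cst$hbar^2
  sm <- sqrt(masses)
  A <- pref * (covariance * outer(sm, sm))
  M <- diag(n) + A
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("numerical error: covariance not positive semi-definite after symmetrization (min eigenvalue %.3g, condition %.3g)",
                 min(ev) - 1, max(ev) / max(min(ev), .Machine$double.eps)), call. = FALSE)
  }
  ld <- sum(log(ev))
  structure(list(entropy = cst$kB / 2 * ld, log_det = ld, n_dof = n), class = "mc_entropy")
}

#' Configurational free energy
#'
#' `F = E - T S`.
#'
#' @param mean_E Mean potential energy, kcal/mol.
#' @param S Entropy, kcal/(mol K) (an `mc_entropy` is also accepted).
#' @param temperature Temperature, K.
#' @return Free energy, kcal/mol.
#' @export
free_energy <- function(mean_E, S, temperature) {
  if (inherits(S, "mc_entropy")) S <- S$entropy
  mean_E - temperature * S
}

# named head-group torsions for the shipped DPPC numbering (Vanderkooi-style
# alpha/beta naming): alpha torsions walk the phosphocholine arm, beta the
# glycerol-to-chain linkages
dppc_named_torsions <- function() {
  list(
    alpha1 = c(5, 6, 7, 8),    # about bond 6-7
    alpha2 = c(4, 5, 6, 7),    # about bond 5-6
    alpha3 = c(3, 4, 5, 6),    # about bond 4-5
    alpha4 = c(2, 3, 4, 5),    # about bond 3-4
    alpha5 = c(1, 2, 3, 4),    # about bond 2-3
    alpha6 = c(44, 1, 2, 3),   # about bond 1-2
    beta1  = c(7, 8, 9, 10),   # about bond 8-9
    beta4  = c(8, 11, 12, 13)  # about bond 11-12
  )
}

#' Torsion angle distribution
#'
#' Occupancy (percent) per bin of a named torsion over all molecules and the
#' selected frames.
#'
#' @param trajectory An `mc_trajectory`.
#' @param torsion_name One of the shipped names (see `names` of the default
#'   `torsion_table`) or a length-4 integer vector of atom ids within the
#'   first molecule.
#' @param bin_width Bin width, degrees (default 5).
#' @param window Frame indices (default: all).
#' @param torsion_table Named list of atom quadruples.
#' @return A data.frame with `angle` (bin centers, degrees in
#'   `[-180, 180)`) and `percent`; percentages sum to 100.
#' @export
torsion_distribution <- function(trajectory, torsion_name, bin_width = 5,
                                 window = NULL, torsion_table = dppc_named_torsions()) {
  if (is.character(torsion_name)) {
    if (!torsion_name %in% names(torsion_table)) {
      stop("unknown torsion name '", torsion_name, "'; known: ",
           paste(names(torsion_table), collapse = ", "), call. = FALSE)
    }
    quad <- torsion_table[[torsion_name]]
  } else {
    quad <- as.integer(torsion_name)
    if (length(quad) != 4L) stop("torsion must be 4 atom ids", call. = FALSE)
  }
  top <- trajectory$topology
  nat_mol <- top$n_atoms / top$n_mol
  frames <- trajectory$frames
  if (is.null(window)) window <- seq_along(frames)
  vals <- unlist(lapply(window, function(w) {
    X <- frames[[w]]$coords
    vapply(seq_len(top$n_mol) - 1L, function(m) {
      q <- quad + m * nat_mol
      dihedral(X[q[1], ], X[q[2], ], X[q[3], ], X[q[4], ]) * 180 / pi
    }, 0)
  }))
  edges <- seq(-180, 180, by = bin_width)
  vals[vals >= 180] <- vals[vals >= 180] - 360
  h <- graphics::hist(vals, breaks = edges, plot = FALSE)
  data.frame(angle = h$mids, percent = 100 * h$counts / length(vals))
}

#' Electron density profile along the bilayer normal
#'
#' Each united atom contributes a Gaussian of its electron count centered at
#' its z coordinate, with variance equal to its van der Waals radius
#' (Angstrom^2), divided by the lateral box area; profiles are averaged over
#' the selected frames. Every frame's profile integrates to the total
#' electron count divided by the box area.
#'
#' @param trajectory An `mc_trajectory` of a bilayer (frames carry a box).
#' @param window Frame indices (default: all).
#' @param dz Grid spacing, Angstrom.
#' @param headgroup_band `c(zmin, zmax)` of |z| (Angstrom, about the profile
#'   center) within which the head-group maxima are searched for `d_hh`.
#' @return A list of class `mc_density`: `z_grid`, `density`
#'   (electrons/Angstrom^3, frame-averaged), `per_frame_integral`
#'   (electrons, after multiplying back by the box area), `d_hh` (Angstrom,
#'   `NA` with a flag if fewer than two maxima resolve).
#' @export
electron_density_profile <- function(trajectory, window = NULL, dz = 0.25,
                                     headgroup_band = c(10, 40)) {
  top <- trajectory$topology
  frames <- trajectory$frames
  if (is.null(window)) window <- seq_along(frames)
  if (is.null(frames[[window[1]]]$box)) {
    stop("electron density profile needs a bilayer trajectory with a box", call. = FALSE)
  }
  ne <- top$atoms$electrons
  s2 <- top$atoms$vdw          # variance equals the vdW radius value
  zs <- unlist(lapply(window, function(w) frames[[w]]$coords[, 3]))
  zmin <- min(zs) - 7 * sqrt(max(s2)); zmax <- max(zs) + 7 * sqrt(max(s2))
  grid <- seq(zmin, zmax, by = dz)
  dens <- matrix(0, length(grid), length(window))
  integ <- numeric(length(window))
  for (wi in seq_along(window)) {
    fr <- frames[[window[wi]]]
    area <- fr$box^2
    z <- fr$coords[, 3]
    prof <- numeric(length(grid))
    for (a in seq_len(top$n_atoms)) {
      prof <- prof + ne[a] * stats::dnorm(grid, z[a], sqrt(s2[a]))
    }
    dens[, wi] <- prof / area
    integ[wi] <- sum(prof) * dz
  }
  avg <- rowMeans(dens)
  d_hh <- .dhh_from_profile(grid, avg, headgroup_band)
  structure(list(z_grid = grid, density = avg, per_frame_integral = integ,
                 d_hh = d_hh$d_hh, d_hh_flag = d_hh$flag),
            class = "mc_density")
}

# peak-to-peak distance across the profile center from a spline-smoothed
# profile restricted to the head-group band
.dhh_from_profile <- function(z, dens, band) {
  zc <- sum(z * dens) / sum(dens)
  sm <- stats::smooth.spline(z, dens, spar = 0.4)
  zz <- seq(min(z), max(z), length.out = 2048)
  dd <- stats::predict(sm, zz)$y
  pick <- function(side) {
    idx <- which(side * (zz - zc) >= band[1] & side * (zz - zc) <= band[2])
    if (length(idx) < 3) return(NA_real_)
    loc <- idx[which.max(dd[idx])]
    zz[loc]
  }
  zp <- pick(+1); zm <- pick(-1)
  if (is.na(zp) || is.na(zm)) {
    return(list(d_hh = NA_real_, flag = "fewer than two resolvable head-group maxima"))
  }
  list(d_hh = zp - zm, flag = NA_character_)
}

#' P-N vector orientation distribution
#'
#' Angle between the phosphorus-to-nitrogen vector of each lipid head group
#' and the bilayer normal (+z), per molecule per frame.
#'
#' @param trajectory An `mc_trajectory`.
#' @param p_atom,n_atom Atom ids of P and N within one molecule (defaults
#'   match the shipped DPPC numbering: N = 1, P = 5).
#' @param bin_width Bin width, degrees.
#' @param window Frame indices (default: all).
#' @return A data.frame with `angle` (bin centers, 0..180) and `percent`.
#' @export
pn_vector_distribution <- function(trajectory, p_atom = 5L, n_atom = 1L,
                                   bin_width = 5, window = NULL) {
  top <- trajectory$topology
  nat_mol <- top$n_atoms / top$n_mol
  frames <- trajectory$frames
  if (is.null(window)) window <- seq_along(frames)
  ang <- unlist(lapply(window, function(w) {
    X <- frames[[w]]$coords
    vapply(seq_len(top$n_mol) - 1L, function(m) {
      v <- X[n_atom + m * nat_mol, ] - X[p_atom + m * nat_mol, ]
      acos(clamp1(v[3] / vnorm3(v))) * 180 / pi
    }, 0)
  }))
  edges <- seq(0, 180, by = bin_width)
  h <- graphics::hist(ang, breaks = edges, plot = FALSE, include.lowest = TRUE)
  data.frame(angle = h$mids, percent = 100 * h$counts / length(ang))
}

#' Area per lipid series
#'
#' Lateral box area divided by the number of lipids per leaflet, per cycle.
#'
#' @param trajectory An `mc_trajectory` of a bilayer.
#' @param lipids_per_leaflet Defaults to half the molecule count.
#' @return Numeric series, Angstrom^2 per lipid (divide by 100 for nm^2).
#' @export
area_per_lipid <- function(trajectory, lipids_per_leaflet = trajectory$topology$n_mol / 2) {
  a <- trajectory$scalars$area
  if (all(is.na(a))) stop("not applicable: monomer trajectory has no box area", call. = FALSE)
  a / lipids_per_leaflet
}

#' Area compressibility modulus from area fluctuations
#'
#' `K_A = k_B T <A> / Var(A)` with `A` the total leaflet area, converted to
#' mN/m.
#'
#' @param area_series Per-lipid area series, Angstrom^2 (from
#'   [area_per_lipid()]).
#' @param temperature Temperature, K.
#' @param lipids_per_leaflet Number of lipids per leaflet (to form the total
#'   leaflet area).
#' @param cap Value reported when the variance underflows (zero fluctuation).
#' @return K_A in mN/m (capped, with a warning, if Var(A) is ~0).
#' @export
compressibility <- function(area_series, temperature, lipids_per_leaflet, cap = 1e6) {
  A <- area_series * lipids_per_leaflet        # total leaflet area, A^2
  vA <- stats::var(A)
  if (!is.finite(vA) || vA < 1e-12) {
    warning("area variance ~ 0: K_A reported as capped value", call. = FALSE)
    return(cap)
  }
  kT_J <- mc_constants$kB_J * temperature
  ka_N_per_m <- kT_J * mean(A) / (vA * 1e-20)  # A^2 / (A^4 * m^2/A^2) = 1/m^2 * ... -> N/m
  ka_N_per_m * 1e3
}

#' Center-of-mass mean square displacement
#'
#' Origin-averaged MSD over all lag origins,
#' `MSD(s) = mean_i mean_{s0} |r_i(s0 + s) - r_i(s0)|^2`, over the lateral
#' (x, y) components of the never-wrapped molecular centers of mass, and the
#' apparent diffusion coefficient from a least-squares line `MSD = 4 D s`
#' on the fit window (Einstein relation in the plane).
#'
#' @param trajectory An `mc_trajectory` (uses its per-cycle COM series), or
#'   an `n_cycles x n_mol x 2-or-3` array of positions.
#' @param fit_window `c(min_lag, max_lag)` in cycles for the linear fit.
#' @param lags Integer lags to evaluate (default: every cycle up to half the
#'   series).
#' @return A list of class `mc_msd`: `lag_grid`, `msd` (Angstrom^2),
#'   `fit_window`, `D_apparent` (Angstrom^2/cycle), `intercept`.
#' @export
msd <- function(trajectory, fit_window = NULL, lags = NULL) {
  com <- if (inherits(trajectory, "mc_trajectory")) trajectory$com else trajectory
  S <- dim(com)[1]
  nmol <- dim(com)[2]
  if (is.null(lags)) lags <- seq_len(max(1L, floor(S / 2)))
  lags <- lags[lags >= 1 & lags < S]
  msd_s <- vapply(lags, function(s) {
    d <- com[(1 + s):S, , 1:2, drop = FALSE] - com[1:(S - s), , 1:2, drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, 0)
  lag_grid <- c(0L, lags)
  msd_all <- c(0, msd_s)
  if (is.null(fit_window)) fit_window <- c(max(1L, floor(max(lags) / 2)), max(lags))
  sel <- which(lag_grid >= fit_window[1] & lag_grid <= fit_window[2])
  if (length(sel) < 3) stop("fit error: fit window shorter than 3 lags", call. = FALSE)
  fit <- stats::lm(msd_all[sel] ~ lag_grid[sel])
  structure(list(lag_grid = lag_grid, msd = msd_all, fit_window = fit_window,
                 D_apparent = unname(stats::coef(fit)[2]) / 4,
                 intercept = unname(stats::coef(fit)[1])),
            class = "mc_msd")
}
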