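# Metropolis driver: sequential per-DOF sweeps (one MC cycle visits every
# plan entry in fixed order), one volume move per cycle in the NPT bilayer
# ensemble, scheduled pair-list refreshes, trajectory and scalar logging.

#' Run configuration
#'
#' @param n_cycles Number of MC cycles (> 0). One cycle visits every move
#'   plan entry once, in plan order, plus one volume move for the bilayer
#'   ensemble.
#' @param temperature Temperature, K (default 323).
#' @param pressure Pressure, atm (default 1; NPT only).
#' @param ensemble `"NVT_monomer"` (no box) or `"NPT_bilayer"` (2D-periodic
#'   cubic cell, volume move every cycle).
#' @param save_every Save a trajectory frame every this many cycles.
#' @param list_update_every Rebuild the neighbor list every this many cycles
#'   (default 10); it is also rebuilt after every accepted volume move.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param cutoff Nonbonded cutoff, Angstrom (`Inf` for the monomer: all
#'   intramolecular pairs are evaluated).
#' @param shell Neighbor-list shell width beyond the cutoff, Angstrom.
#' @param max_dlnV Maximum |d ln V| per volume move.
#' @param dielectric Optional `mc_dielectric` overriding the parameter file.
#' @param dielectric_mode `"pair"` (screening by interatomic distance,
#'   default), `"constant"` (epsilon = 1) or `"interface"` (screening by the
#'   pair midpoint's height above the bilayer midplane).
#' @param use_jacobian Diagnostic switch. `FALSE` drops the volume-element
#'   (Jacobian) correction from the acceptance rule, which provably skews
#'   angle distributions; only useful to demonstrate why the correction is
#'   required. Never disable it in production runs.
#' @return A list of class `mc_runconfig`.
#' @export
run_config <- function(n_cycles, temperature = 323, pressure = 1,
                       ensemble = c("NVT_monomer", "NPT_bilayer"),
                       save_every = 100L, list_update_every = 10L, seed = 1L,
                       cutoff = NULL, shell = 10, max_dlnV = 0.02,
                       dielectric = NULL, dielectric_mode = "pair",
                       use_jacobian = TRUE) {
  ensemble <- match.arg(ensemble)
  if (n_cycles <= 0) stop("n_cycles must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (list_update_every < 1) stop("list_update_every must be >= 1", call. = FALSE)
  if (is.null(cutoff)) cutoff <- if (ensemble == "NVT_monomer") Inf else 10
  structure(list(n_cycles = as.integer(n_cycles), temperature = temperature,
                 pressure = pressure, ensemble = ensemble,
                 save_every = as.integer(save_every),
                 list_update_every = as.integer(list_update_every),
                 seed = as.integer(seed), cutoff = cutoff, shell = shell,
                 max_dlnV = max_dlnV, dielectric = dielectric,
                 dielectric_mode = dielectric_mode,
                 use_jacobian = isTRUE(use_jacobian)),
            class = "mc_runconfig")
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Executes `n_cycles` sweeps. Within a sweep every plan entry is visited in
#' fixed sequential order with sequential energy updating; for the NPT
#' bilayer ensemble one volume move is attempted per cycle. The neighbor
#' list is rebuilt every `list_update_every` cycles and after every accepted
#' volume move. Identical seeds give identical trajectories.
#'
#' @param configuration Start `mc_config`; must satisfy the bond-length
#'   invariants.
#' @param topology An `mc_topology`.
#' @param plan An `mc_moveplan`.
#' @param config An `mc_runconfig` from [run_config()].
#' @param quiet Suppress the per-10^3-cycle acceptance log.
#' @param observer Optional `function(coords)` returning one number, called
#'   after every attempted move; the values are returned as
#'   `per_move_observations`. Used for per-move convergence diagnostics such
#'   as sampled marginal distributions.
#' @return An object of class `mc_trajectory`: saved frames with cycle
#'   stamps, per-cycle scalars (potential energy, enthalpy for NPT, volume,
#'   area), per-cycle molecular centers of mass (never wrapped, for MSD),
#'   per-class acceptance statistics, and the topology and run configuration.
#' @export
run_mc <- function(configuration, topology, plan, config, quiet = TRUE,
                   observer = NULL) {
  stopifnot(inherits(configuration, "mc_config"), inherits(topology, "mc_topology"),
            inherits(plan, "mc_moveplan"), inherits(config, "mc_runconfig"))
  if (plan$n_atoms != topology$n_atoms) {
    # single-molecule plans apply per molecule of a replicated system
    if (topology$n_atoms %% plan$n_atoms == 0L) {
      plan <- replicate_plan(plan, topology)
    } else {
      stop("plan and topology disagree on atom count", call. = FALSE)
    }
  }
  check_bonds(configuration, topology, tol = 1e-9)
  npt <- config$ensemble == "NPT_bilayer"
  if (npt && is.null(configuration$box)) stop("NPT ensemble requires a periodic box", call. = FALSE)

  set.seed(config$seed)
  model <- energy_model(topology, dielectric = config$dielectric,
                        dielectric_mode = config$dielectric_mode)
  coords <- configuration$coords
  box <- configuration$box
  periodic <- configuration$periodic
  masses <- topology$atoms$mass
  mol_mass <- as.numeric(rowsum(matrix(masses), topology$mol))

  mkconf <- function() structure(list(coords = coords, box = box, periodic = periodic),
                                 class = "mc_config")
  nlist <- build_neighbor_list(mkconf(), topology, config$cutoff, config$shell, model)
  E <- total_energy(mkconf(), nlist, topology, model)

  # per-entry delta-energy caches (bonded term indices, within-set pairs),
  # built for the full moved set including external riders in rider order
  for (k in seq_along(plan$entries)) {
    e <- plan$entries[[k]]
    full_moved <- switch(e$class,
      breakage   = c(e$atom, vapply(e$closures, `[[`, 0L, "c"), e$riders$atom),
      crankshaft = c(e$atom, e$riders$atom),
      c(e$moved, e$riders$atom))
    plan$entries[[k]]$cache <- build_delta_cache(as.integer(full_moved), model)
  }

  n_entries <- length(plan$entries)
  classes <- vapply(plan$entries, `[[`, "", "class")
  cls_levels <- unique(c(classes, if (npt) "volume"))
  att <- acc <- stats::setNames(numeric(length(cls_levels)), cls_levels)
  cls_idx <- match(classes, cls_levels)
  vol_idx <- match("volume", cls_levels)

  nc <- config$n_cycles
  scal_E <- numeric(nc); scal_V <- numeric(nc); scal_A <- numeric(nc); scal_H <- numeric(nc)
  obs <- if (!is.null(observer)) numeric(nc * (n_entries + npt)) else NULL
  obs_i <- 0L
  com <- array(NA_real_, c(nc, topology$n_mol, 3L))
  frames <- list(list(coords = coords, box = box, cycle = 0L))

  for (cyc in seq_len(nc)) {
    for (k in seq_len(n_entries)) {
      entry <- plan$entries[[k]]
      conf <- mkconf()
      prop <- switch(entry$class,
        breakage   = propose_breakage_move(conf, entry, nlist = nlist, model = model),
        crankshaft = propose_crankshaft(conf, entry, nlist = nlist, model = model),
        torsion    = ,
        bond_angle = propose_internal(conf, entry, nlist = nlist, model = model))
      ci <- cls_idx[k]
      att[ci] <- att[ci] + 1
      if (!config$use_jacobian) {
        prop$jacobian_ratio <- 1
        prop$selection_ratio <- 1
      }
      if (metropolis_accept(prop, config$temperature)) {
        acc[ci] <- acc[ci] + 1
        coords[prop$moved, ] <- prop$trial
        E <- E + prop$delta_E
      }
      if (!is.null(observer)) { obs_i <- obs_i + 1L; obs[obs_i] <- observer(coords) }
    }
    if (npt) {
      prop <- propose_volume_move(mkconf(), config$max_dlnV, topology$n_mol,
                                  config$pressure, config$temperature,
                                  topology, nlist, model)
      att[vol_idx] <- att[vol_idx] + 1
      if (metropolis_accept(prop, config$temperature)) {
        acc[vol_idx] <- acc[vol_idx] + 1
        coords <- prop$trial
        box <- prop$extra$box_new
        E <- E + prop$delta_E
        nlist <- build_neighbor_list(mkconf(), topology, config$cutoff, config$shell, model)
      }
      if (!is.null(observer)) { obs_i <- obs_i + 1L; obs[obs_i] <- observer(coords) }
    }
    if (cyc %% config$list_update_every == 0L) {
      nlist <- build_neighbor_list(mkconf(), topology, config$cutoff, config$shell, model)
    } else {
      nlist$age <- nlist$age + 1L
    }
    # CBLA watchdog
    dev <- bond_deviation(mkconf(), topology)
    if (dev > 1e-6) {
      dump <- tempfile("cbla_violation_", fileext = ".pdb")
      write_pdb(mkconf(), topology, dump)
      stop(sprintf("CBLA violation at cycle %d: relative bond deviation %.3g > 1e-6; frame dumped to %s",
                   cyc, dev, dump), call. = FALSE)
    }
    scal_E[cyc] <- E
    scal_V[cyc] <- if (!is.null(box)) box^3 else NA_real_
    scal_A[cyc] <- if (!is.null(box)) box^2 else NA_real_
    scal_H[cyc] <- if (npt) E + config$pressure * box^3 * mc_constants$atm_A3 else NA_real_
    com[cyc, , ] <- rowsum(coords * masses, topology$mol) / mol_mass
    if (cyc %% config$save_every == 0L) {
      frames <- c(frames, list(list(coords = coords, box = box, cycle = cyc)))
    }
    if (!quiet && cyc %% 1000L == 0L) {
      message(sprintf("cycle %d: E = %.3f kcal/mol; acceptance %s", cyc, E,
                      paste(sprintf("%s %.2f", cls_levels, acc / pmax(att, 1)), collapse = ", ")))
    }
  }

  scalars <- data.frame(cycle = seq_len(nc), energy = scal_E, enthalpy = scal_H,
                        volume = scal_V, area = scal_A)
  structure(list(
    frames = frames,
    scalars = scalars,
    com = com,
    acceptance = data.frame(class = cls_levels, attempts = as.numeric(att),
                            accepted = as.numeric(acc)),
    topology = topology,
    config = config,
    per_move_observations = obs,
    final = list(coords = coords, box = box, energy = E)
  ), class = "mc_trajectory")
}

# replicate a single-molecule plan across all molecules of a system
replicate_plan <- function(plan, topology) {
  nat <- plan$n_atoms
  nmol <- topology$n_atoms %/% nat
  raw <- list()
  for (m in seq_len(nmol) - 1L) {
    off <- m * nat
    for (e in plan$entries) {
      raw <- c(raw, list(switch(e$class,
        breakage   = list(class = "breakage", atom = e$atom + off, step = e$step),
        crankshaft = list(class = "crankshaft", atom = e$atom + off, step = e$step * 180 / pi),
        torsion    = list(class = "torsion", axis = e$axis + off, step = e$step * 180 / pi,
                          explicit = if (length(e$moved)) e$moved + off else NULL),
        bond_angle = list(class = "bond_angle", triple = e$triple + off, step = e$step * 180 / pi)
      )))
    }
  }
  # raw angles are re-parsed in degrees by compile via load path; compile
  # expects radians already for crankshaft/torsion/bond_angle steps
  for (i in seq_along(raw)) {
    if (raw[[i]]$class != "breakage") raw[[i]]$step <- raw[[i]]$step * pi / 180
  }
  compile_move_plan(raw, topology)
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> %d cycles, %d saved frames, %d atoms, %d molecule(s)\n",
              nrow(x$scalars), length(x$frames), x$topology$n_atoms, x$topology$n_mol))
  a <- x$acceptance
  for (r in seq_len(nrow(a))) {
    cat(sprintf("  %-10s %8.0f attempts, %5.1f%% accepted\n", a$class[r], a$attempts[r],
                100 * a$accepted[r] / max(a$attempts[r], 1)))
  }
  invisible(x)
}
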