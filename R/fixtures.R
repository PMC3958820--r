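# Programmatic test systems. Toy potentials are chosen so that reference
# distributions are computable by quadrature: a single harmonic bond angle,
# a single Ryckaert-Bellemans torsion, or no interactions at all.

.fixture_atoms <- function(n, name_prefix = "C") {
  data.frame(id = seq_len(n),
             name = paste0(name_prefix, seq_len(n)),
             type = "CT", element = "C",
             mass = 14.027, electrons = 8, vdw = 2.0, charge = 0,
             stringsAsFactors = FALSE)
}

.fixture_params <- function(name, atoms, bonds, angles, torsions, rb, build,
                            lj_eps = 0) {
  empty_t <- data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                        v = numeric(0), n = numeric(0), gamma = numeric(0))
  empty_rb <- data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                         c0 = numeric(0), c1 = numeric(0), c2 = numeric(0),
                         c3 = numeric(0), c4 = numeric(0), c5 = numeric(0))
  empty_a <- data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                        k_theta = numeric(0), theta0 = numeric(0))
  structure(list(
    name = name,
    defaults = list(dielectric_d = 78, dielectric_s = 0.654,
                    lj14_scale = 0.5, coul14_scale = 1 / 1.2,
                    coulomb_constant = mc_constants$coulomb),
    atoms = atoms, bonds = bonds,
    angles = if (is.null(angles)) empty_a else angles,
    torsions = if (is.null(torsions)) empty_t else torsions,
    rb = if (is.null(rb)) empty_rb else rb,
    lj = data.frame(type = "CT", rmin_half = 2.0, epsilon = lj_eps,
                    stringsAsFactors = FALSE),
    externals = data.frame(atom = numeric(0), parent = numeric(0),
                           ref1 = numeric(0), ref2 = numeric(0)),
    main_chain = list(seq_len(nrow(atoms))),
    build = build
  ), class = "mc_params")
}

# z-matrix for an n-atom chain with equal bond lengths and angles, torsions
# slightly off planar so no closure geometry starts degenerate
.chain_build <- function(n, len, theta0, torsion = 170 * pi / 180) {
  data.frame(atom = seq_len(n),
             r1 = c(0, 1, 2, seq_len(max(0, n - 3)) + 2),
             r2 = c(0, 0, 1, seq_len(max(0, n - 3)) + 1),
             r3 = c(0, 0, 0, seq_len(max(0, n - 3))),
             length = c(0, rep(len, n - 1)),
             angle = c(0, 0, rep(theta0, n - 2)),
             torsion = c(0, 0, 0, rep(torsion, max(0, n - 3))))
}

#' Generate a toy or DPPC fixture system
#'
#' @param kind One of `"linear_chain"`, `"branched_chain"`, `"ideal_gas"`,
#'   `"dppc_monomer"`, `"dppc_bilayer"`.
#' @param n_atoms Atoms for chain fixtures (>= 3) or molecules for the ideal
#'   gas.
#' @param bond_length Fixed bond length, Angstrom.
#' @param angle_k Harmonic constant of the single bond-angle potential at
#'   vertex 2 (`E = k (theta - theta0)^2`), kcal/mol/rad^2; 0 disables it.
#' @param angle_theta0 Equilibrium angle, radians.
#' @param rb_coefficients Optional length-6 RB coefficients for the torsion
#'   1-2-3-4 of a chain fixture.
#' @param breakage_step,crank_step,torsion_step,angle_step Move-plan step
#'   sizes (Angstrom / radians).
#' @param seed Seed (ideal-gas box placement and bilayer rotations).
#' @param box Box edge for the ideal gas, Angstrom.
#' @param n_per_leaflet,lattice_spacing Bilayer fixture geometry.
#' @param dir If non-NULL, the parameter, plan and PDB files are written
#'   there (deterministically) and their paths returned.
#' @return A list: `topology`, `conf`, `plan`, `params`, and `files` (NULL
#'   unless `dir` was given).
#' @export
generate_fixture <- function(kind = c("linear_chain", "branched_chain", "ideal_gas",
                                      "dppc_monomer", "dppc_bilayer"),
                             n_atoms = 4L, bond_length = 1.53,
                             angle_k = 0.5, angle_theta0 = 109.47 * pi / 180,
                             rb_coefficients = NULL,
                             breakage_step = 0.8, crank_step = pi,
                             torsion_step = pi, angle_step = 0.8,
                             seed = 1L, box = 95,
                             n_per_leaflet = 4L, lattice_spacing = 10,
                             dir = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    linear_chain = {
      n <- as.integer(n_atoms)
      if (n < 3L) stop("linear_chain needs n_atoms >= 3", call. = FALSE)
      atoms <- .fixture_atoms(n)
      bonds <- data.frame(i = seq_len(n - 1L), j = 2:n, length = bond_length)
      angles <- if (angle_k > 0) {
        data.frame(i = 1, j = 2, k = 3, k_theta = angle_k, theta0 = angle_theta0)
      } else NULL
      rb <- if (!is.null(rb_coefficients)) {
        stopifnot(length(rb_coefficients) == 6L, n >= 4L)
        as.data.frame(c(list(i = 1, j = 2, k = 3, l = 4),
                        stats::setNames(as.list(rb_coefficients), paste0("c", 0:5))))
      } else NULL
      params <- .fixture_params("linear_chain", atoms, bonds, angles, NULL, rb,
                                .chain_build(n, bond_length, angle_theta0))
      topology <- build_topology(params)
      conf <- build_monomer_start(topology)
      entries <- list()
      for (a in 2:(n - 1L)) {
        entries <- c(entries,
                     list(list(class = "breakage", atom = a, step = breakage_step)),
                     list(list(class = "crankshaft", atom = a, step = crank_step)))
      }
      if (n >= 5L) {  # terminal internal-coordinate moves mirror the lipid plan
        entries <- c(entries,
          list(list(class = "torsion", axis = c(n - 2L, n - 1L), step = torsion_step, explicit = NULL),
               list(class = "bond_angle", triple = c(n - 2L, n - 1L, n), step = angle_step),
               list(class = "torsion", axis = c(3L, 2L), step = torsion_step, explicit = NULL),
               list(class = "bond_angle", triple = c(3L, 2L, 1L), step = angle_step)))
      }
      plan <- compile_move_plan(entries, topology)
      list(topology = topology, conf = conf, plan = plan, params = params)
    },
    branched_chain = {
      # 1-2-3-4 with a branch 3-5: exercises branch-point breakage closures
      atoms <- .fixture_atoms(5L)
      bonds <- data.frame(i = c(1, 2, 3, 3), j = c(2, 3, 4, 5), length = bond_length)
      angles <- if (angle_k > 0) {
        data.frame(i = 1, j = 2, k = 3, k_theta = angle_k, theta0 = angle_theta0)
      } else NULL
      build <- data.frame(atom = 1:5,
                          r1 = c(0, 1, 2, 3, 3), r2 = c(0, 0, 1, 2, 2), r3 = c(0, 0, 0, 1, 1),
                          length = c(0, rep(bond_length, 4)),
                          angle = c(0, 0, rep(angle_theta0, 3)),
                          torsion = c(0, 0, 0, 170 * pi / 180, 60 * pi / 180))
      params <- .fixture_params("branched_chain", atoms, bonds, angles, NULL, NULL, build)
      topology <- build_topology(params)
      conf <- build_monomer_start(topology)
      entries <- list(
        list(class = "breakage", atom = 3L, step = breakage_step),
        list(class = "crankshaft", atom = 2L, step = crank_step),
        list(class = "torsion", axis = c(2L, 3L), step = torsion_step, explicit = NULL))
      plan <- compile_move_plan(entries, topology)
      list(topology = topology, conf = conf, plan = plan, params = params)
    },
    ideal_gas = {
      n <- as.integer(n_atoms)
      atoms <- .fixture_atoms(n, "AR")
      bonds <- data.frame(i = numeric(0), j = numeric(0), length = numeric(0))
      params <- .fixture_params("ideal_gas", atoms, bonds, NULL, NULL, NULL,
                                data.frame(atom = numeric(0), r1 = numeric(0), r2 = numeric(0),
                                           r3 = numeric(0), length = numeric(0),
                                           angle = numeric(0), torsion = numeric(0)))
      topology <- build_topology(params)
      old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      coords <- matrix(stats::runif(3L * n, 0.1 * box, 0.9 * box), n, 3L)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      conf <- mc_config(coords, box = box)
      plan <- compile_move_plan(list(), topology)
      list(topology = topology, conf = conf, plan = plan, params = params)
    },
    dppc_monomer = {
      topology <- build_dppc_topology()
      conf <- build_monomer_start(topology)
      plan <- load_move_plan(dppc_plan_file(), topology)
      list(topology = topology, conf = conf, plan = plan, params = topology$params)
    },
    dppc_bilayer = {
      topology <- build_dppc_topology()
      plan <- load_move_plan(dppc_plan_file(), topology)
      bl <- build_bilayer_start(topology, n_per_leaflet, lattice_spacing, seed = seed)
      list(topology = bl$topology, conf = bl$conf, plan = plan, params = topology$params)
    })
  out$kind <- kind
  out$files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prm <- file.path(dir, paste0(kind, ".prm"))
    pdb <- file.path(dir, paste0(kind, ".pdb"))
    write_parameter_file(out$params, prm)
    write_pdb(out$conf, out$topology, pdb)
    out$files <- c(params = prm, pdb = pdb)
  }
  out
}
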