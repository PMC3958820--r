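# two free (non-bonded) atoms with controllable LJ/charge, in an optional box
two_atom_system <- function(eps = 0, rmin_half = 2, q = c(0, 0), sep = 4, box = NULL) {
  atoms <- data.frame(id = 1:2, name = c("A1", "A2"), type = "AT", element = "C",
                      mass = 14, electrons = 8, vdw = 2, charge = q,
                      stringsAsFactors = FALSE)
  params <- structure(list(
    name = "pair", defaults = list(dielectric_d = 78, dielectric_s = 0.654,
                                   lj14_scale = 0.5, coul14_scale = 1 / 1.2,
                                   coulomb_constant = 332.0636),
    atoms = atoms,
    bonds = data.frame(i = numeric(0), j = numeric(0), length = numeric(0)),
    angles = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                        k_theta = numeric(0), theta0 = numeric(0)),
    torsions = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                          v = numeric(0), n = numeric(0), gamma = numeric(0)),
    rb = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                    c0 = numeric(0), c1 = numeric(0), c2 = numeric(0),
                    c3 = numeric(0), c4 = numeric(0), c5 = numeric(0)),
    lj = data.frame(type = "AT", rmin_half = rmin_half, epsilon = eps,
                    stringsAsFactors = FALSE),
    externals = data.frame(atom = numeric(0), parent = numeric(0),
                           ref1 = numeric(0), ref2 = numeric(0)),
    main_chain = list(), build = data.frame()
  ), class = "mc_params")
  top <- build_topology(params)
  conf <- mc_config(rbind(c(0, 0, 0), c(sep, 0, 0)), box = box)
  list(top = top, conf = conf)
}

test_that("the sigmoidal dielectric reproduces its published checkpoints", {
  expect_equal(dielectric(10, dielectric_params(78, 0.65)), 74.69, tolerance = 0.01 / 74.69)
  expect_equal(dielectric(10, dielectric_params(78, 0.15)), 15.72, tolerance = 0.01 / 15.72)
  expect_equal(dielectric(0, dielectric_params(42, 0.3)), 1)       # analytic r = 0 limit
  expect_error(dielectric(-1), "r must be")
})

test_that("the dielectric is non-decreasing and bounded on [0, 100]", {
  for (s in c(0.15, 0.354, 0.654, 1.2)) {
    v <- dielectric(seq(0, 100, by = 0.25), dielectric_params(78, s))
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= 1 - 1e-12 & v <= 78 + 1e-12))
  }
})

test_that("two neutral atoms at the LJ minimum distance contribute -epsilon", {
  s <- two_atom_system(eps = 0.2, rmin_half = 1.9, sep = 3.8)
  nl <- build_neighbor_list(s$conf, s$top, cutoff = Inf, shell = 0)
  expect_equal(nonbonded_energy(s$conf, nl, s$top), -0.2, tolerance = 1e-12)
})

test_that("unit charges at 10 Angstrom with epsilon = 1 give the Coulomb constant / 10", {
  s <- two_atom_system(q = c(1, 1), sep = 10)
  nl <- build_neighbor_list(s$conf, s$top, cutoff = Inf, shell = 0)
  model <- lipidmc:::energy_model(s$top, dielectric_mode = "constant")
  expect_equal(nonbonded_energy(s$conf, nl, s$top, model), 332.0636 / 10, tolerance = 1e-12)
})

test_that("pairs beyond the cutoff contribute nothing", {
  s <- two_atom_system(eps = 0.2, q = c(1, -1), sep = 10.5, box = 50)
  nl <- build_neighbor_list(s$conf, s$top, cutoff = 10, shell = 10)
  expect_equal(nonbonded_energy(s$conf, nl, s$top), 0)
})

test_that("pair distances below 0.1 Angstrom raise an overlap error", {
  s <- two_atom_system(eps = 0.2, sep = 0.05)
  nl <- build_neighbor_list(s$conf, s$top, cutoff = Inf, shell = 0)
  expect_error(nonbonded_energy(s$conf, nl, s$top), "overlap")
})

test_that("bonded energy at the equilibrium start reduces to torsion offsets", {
  fx <- dppc_fixture()
  model <- lipidmc:::energy_model(fx$topology)
  e_all <- bonded_energy(fx$conf, fx$topology, model)
  e_tor <- lipidmc:::.bonded_terms_energy(fx$conf$coords, model, integer(0), NULL, NULL)
  expect_equal(e_all, e_tor, tolerance = 1e-12)   # harmonic angle terms vanish
  expect_gt(e_tor, 0)
})

test_that("a scanned Ryckaert-Bellemans torsion matches direct polynomial evaluation", {
  rbc <- c(2.218, 2.906, -3.136, -0.731, 6.271, -7.527)
  fx <- generate_fixture("linear_chain", n_atoms = 4, angle_k = 0, rb_coefficients = rbc)
  top <- fx$topology
  X0 <- fx$conf$coords
  ax <- X0[3, ] - X0[2, ]
  ax <- ax / sqrt(sum(ax^2))
  for (target in seq(0, 350, by = 25)) {
    phi0 <- dihedral(X0[1, ], X0[2, ], X0[3, ], X0[4, ])
    X <- X0
    X[4, ] <- rotate_about_axis(X0[4, ], X0[2, ], ax, target * pi / 180 - phi0)
    conf <- mc_config(X)
    phi <- dihedral(X[1, ], X[2, ], X[3, ], X[4, ])
    cpsi <- -cos(phi)                       # psi = phi - 180, trans -> 0
    e_expect <- sum(rbc * cpsi^(0:5))       # independent per-term summation
    expect_equal(bonded_energy(conf, top), e_expect, tolerance = 1e-9)
    if (abs(abs(phi) - pi) < 1e-9) {
      expect_equal(bonded_energy(conf, top), sum(rbc), tolerance = 1e-9)  # value at 180
    }
  }
})

test_that("delta_energy equals the full-recompute difference", {
  fx <- dppc_fixture()
  top <- fx$topology
  model <- lipidmc:::energy_model(top)
  nl <- build_neighbor_list(fx$conf, top, cutoff = Inf, shell = 0, model = model)
  e0 <- total_energy(fx$conf, nl, top, model)

  # no-op move
  expect_equal(delta_energy(fx$conf, fx$conf$coords[5, , drop = FALSE], 5L, nl, top, model), 0)

  set.seed(8)
  for (rep in 1:20) {
    moved <- sample(50, sample(1:4, 1))
    trial <- fx$conf$coords[moved, , drop = FALSE] + matrix(rnorm(3 * length(moved), 0, 0.05),
                                                            ncol = 3)
    dE <- delta_energy(fx$conf, trial, moved, nl, top, model)
    X2 <- fx$conf$coords
    X2[moved, ] <- trial
    conf2 <- mc_config(X2)
    nl2 <- build_neighbor_list(conf2, top, cutoff = Inf, shell = 0, model = model)
    dE_full <- total_energy(conf2, nl2, top, model) - e0
    expect_equal(dE, dE_full, tolerance = 1e-8)
  }
})

test_that("delta_energy stays exact when an atom crosses the cutoff boundary", {
  s <- two_atom_system(eps = 0.3, q = c(0.5, -0.5), sep = 9.8, box = 60)
  model <- lipidmc:::energy_model(s$top)
  nl <- build_neighbor_list(s$conf, s$top, cutoff = 10, shell = 10, model = model)
  e0 <- total_energy(s$conf, nl, s$top, model)
  trial <- matrix(c(10.7, 0, 0), 1, 3)           # atom 2 moves outside the cutoff
  dE <- delta_energy(s$conf, trial, 2L, nl, s$top, model)
  X2 <- s$conf$coords; X2[2, ] <- trial
  conf2 <- mc_config(X2, box = 60)
  nl2 <- build_neighbor_list(conf2, s$top, cutoff = 10, shell = 10, model = model)
  expect_equal(dE, total_energy(conf2, nl2, s$top, model) - e0, tolerance = 1e-10)
})

test_that("neighbor list classifies pairs by minimum-image distance", {
  s5 <- two_atom_system(sep = 5, box = 60)
  nl <- build_neighbor_list(s5$conf, s5$top, cutoff = 10, shell = 10)
  expect_equal(nrow(nl$pairs_inner), 1L)
  expect_equal(nrow(nl$pairs_shell), 0L)

  s15 <- two_atom_system(sep = 15, box = 60)
  nl <- build_neighbor_list(s15$conf, s15$top, cutoff = 10, shell = 10)
  expect_equal(nrow(nl$pairs_inner), 0L)
  expect_equal(nrow(nl$pairs_shell), 1L)

  # raw separation 10.1 in a 20 box wraps to 9.9: inner by minimum image;
  # brute-force check over explicit images
  s <- two_atom_system(sep = 10.1, box = 20)
  nl <- suppressWarnings(build_neighbor_list(s$conf, s$top, cutoff = 10, shell = 5))
  expect_equal(nrow(nl$pairs_inner), 1L)
  imgs <- expand.grid(ix = -2:2, iy = -2:2)
  dmin <- min(sqrt((10.1 + 20 * imgs$ix)^2 + (20 * imgs$iy)^2))
  expect_equal(dmin, 9.9, tolerance = 1e-12)
})

test_that("neighbor-list energies equal brute-force minimum-image sums on random gases", {
  # independent brute force: explicit double loop over all pairs
  brute <- function(X, box, eps, rmin_half, cutoff) {
    n <- nrow(X); e <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- X[i, ] - X[j, ]
      d[1:2] <- d[1:2] - box * round(d[1:2] / box)
      r2 <- sum(d^2)
      if (r2 < cutoff^2) {
        s6 <- ((2 * rmin_half)^2 / r2)^3
        e <- e + eps * (s6^2 - 2 * s6)
      }
    }
    e
  }
  atoms <- data.frame(id = 1:30, name = paste0("A", 1:30), type = "AT",
                      element = "C", mass = 14, electrons = 8, vdw = 2, charge = 0,
                      stringsAsFactors = FALSE)
  params <- structure(list(
    name = "gas", defaults = list(),
    atoms = atoms,
    bonds = data.frame(i = numeric(0), j = numeric(0), length = numeric(0)),
    angles = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                        k_theta = numeric(0), theta0 = numeric(0)),
    torsions = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                          v = numeric(0), n = numeric(0), gamma = numeric(0)),
    rb = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                    c0 = numeric(0), c1 = numeric(0), c2 = numeric(0),
                    c3 = numeric(0), c4 = numeric(0), c5 = numeric(0)),
    lj = data.frame(type = "AT", rmin_half = 1.5, epsilon = 0.1, stringsAsFactors = FALSE),
    externals = data.frame(atom = numeric(0), parent = numeric(0),
                           ref1 = numeric(0), ref2 = numeric(0)),
    main_chain = list(), build = data.frame()
  ), class = "mc_params")
  top <- build_topology(params)
  model <- lipidmc:::energy_model(top)
  set.seed(9)
  box <- 30
  n_checked <- 0
  for (rep in 1:1000) {
    n <- sample(5:30, 1)
    X <- matrix(0, 30, 3)
    X[1:n, ] <- matrix(runif(3 * n, 0, box), n, 3)
    park <- setdiff(1:30, 1:n)   # park unused atoms far away along +z
    if (length(park)) X[park, ] <- cbind(0, 0, 1e4 + 50 * seq_along(park))
    conf <- mc_config(X, box = box)
    nl <- suppressWarnings(build_neighbor_list(conf, top, cutoff = 8, shell = 4, model = model))
    e_pkg <- tryCatch(nonbonded_energy(conf, nl, top, model), error = function(e) NA)
    if (is.na(e_pkg)) next   # overlap error: brute force would diverge too
    expect_equal(e_pkg, brute(X, box, 0.1, 1.5, 8), tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 900)
})

test_that("rigid translation with wrapping leaves the total energy unchanged", {
  bl <- generate_fixture("dppc_bilayer", n_per_leaflet = 4, lattice_spacing = 10, seed = 3)
  model <- lipidmc:::energy_model(bl$topology)
  nl <- suppressWarnings(build_neighbor_list(bl$conf, bl$topology, 10, 10, model))
  e0 <- total_energy(bl$conf, nl, bl$topology, model)
  X2 <- sweep(bl$conf$coords, 2, c(7.3, -4.1, 0), "+")
  conf2 <- mc_config(X2, box = bl$conf$box)
  nl2 <- suppressWarnings(build_neighbor_list(conf2, bl$topology, 10, 10, model))
  e1 <- total_energy(conf2, nl2, bl$topology, model)
  expect_equal(e1, e0, tolerance = 1e-8 * abs(e0))
})
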