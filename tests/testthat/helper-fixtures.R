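# shared fixtures; built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

dppc_fixture <- function() cached_fixture("dppc", function() generate_fixture("dppc_monomer"))

# minimal synthetic trajectory object for analysis functions
make_traj <- function(frames_coords, topology, box = NULL, com = NULL,
                      scalars = NULL, temperature = 323) {
  frames <- lapply(seq_along(frames_coords), function(k) {
    list(coords = frames_coords[[k]], box = box, cycle = k - 1L)
  })
  structure(list(frames = frames, scalars = scalars, com = com,
                 topology = topology,
                 config = list(temperature = temperature)),
            class = "mc_trajectory")
}

# a bare one-bead-per-molecule topology for synthetic analysis fixtures
point_topology <- function(n, electrons = 8, vdw = 2, mass = 14) {
  atoms <- data.frame(id = seq_len(n), name = paste0("X", seq_len(n)),
                      type = "CT", element = "C", mass = mass,
                      electrons = electrons, vdw = vdw, charge = 0,
                      stringsAsFactors = FALSE)
  params <- structure(list(
    name = "points", defaults = list(),
    atoms = atoms,
    bonds = data.frame(i = numeric(0), j = numeric(0), length = numeric(0)),
    angles = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                        k_theta = numeric(0), theta0 = numeric(0)),
    torsions = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                          v = numeric(0), n = numeric(0), gamma = numeric(0)),
    rb = data.frame(i = numeric(0), j = numeric(0), k = numeric(0), l = numeric(0),
                    c0 = numeric(0), c1 = numeric(0), c2 = numeric(0),
                    c3 = numeric(0), c4 = numeric(0), c5 = numeric(0)),
    lj = data.frame(type = "CT", rmin_half = 2, epsilon = 0, stringsAsFactors = FALSE),
    externals = data.frame(atom = numeric(0), parent = numeric(0),
                           ref1 = numeric(0), ref2 = numeric(0)),
    main_chain = list(), build = data.frame()
  ), class = "mc_params")
  build_topology(params)
}

# exact Boltzmann CDF of a bond angle with measure sin(theta) exp(-beta*k*(theta-th0)^2)
exact_angle_cdf <- function(k_th, th0, temperature = 323) {
  beta <- 1 / (0.0019872041 * temperature)
  grid <- seq(1e-5, pi - 1e-5, length.out = 4001)
  dens <- sin(grid) * exp(-beta * k_th * (grid - th0)^2)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  approxfun(grid, cdf, yleft = 0, yright = 1)
}

ks_distance <- function(samples, cdf_fun) {
  s <- sort(samples)
  n <- length(s)
  max(abs(seq_len(n) / n - cdf_fun(s)))
}

kB <- 0.0019872041
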