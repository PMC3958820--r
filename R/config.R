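# Configurations: Cartesian coordinates plus the (optional) 2D-periodic
# cubic cell, and construction of monomer and crystalline-bilayer starts.

#' Create a configuration object
#'
#' @param coords n x 3 numeric matrix of Cartesian coordinates, Angstrom.
#' @param box Cubic cell edge length (Angstrom), or `NULL` for non-periodic
#'   (monomer) systems.
#' @param periodic Logical 3-vector: which axes wrap. The bilayer model is
#'   periodic in x and y only; the bilayer normal is +z.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(coords, box = NULL, periodic = c(TRUE, TRUE, FALSE)) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  if (!all(is.finite(coords))) stop("configuration error: non-finite coordinates", call. = FALSE)
  structure(list(coords = coords, box = box, periodic = periodic), class = "mc_config")
}

#' Check the constant-bond-length invariant of a configuration
#'
#' @param conf An `mc_config`.
#' @param topology An `mc_topology`.
#' @param tol Maximum allowed relative deviation of any bond length.
#' @return Invisibly, the maximum relative deviation. Errors if above `tol`.
#' @export
check_bonds <- function(conf, topology, tol = 1e-9) {
  dev <- bond_deviation(conf, topology)
  if (dev > tol) {
    stop(sprintf("configuration error: bond-length deviation %.3g exceeds %.3g", dev, tol),
         call. = FALSE)
  }
  invisible(dev)
}

# max relative |r_ij - l_ij| / l_ij over all bonds
bond_deviation <- function(conf, topology) {
  b <- topology$bonds
  if (!nrow(b)) return(0)
  d <- conf$coords[b$i, , drop = FALSE] - conf$coords[b$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  max(abs(r - b$length) / b$length)
}

#' Build the all-trans monomer start conformation
#'
#' Constructs the molecule from the equilibrium internal coordinates in the
#' parameter file's z-matrix: every bond at its fixed length, every placed
#' angle at its equilibrium value, chain torsions at 180 degrees, yielding
#' straight (all-trans) fatty acyl chains.
#'
#' @param topology An `mc_topology` for a single molecule.
#' @return An `mc_config` with no periodic box.
#' @export
build_monomer_start <- function(topology) {
  stopifnot(inherits(topology, "mc_topology"))
  bd <- topology$params$build
  n <- topology$n_atoms
  if (nrow(bd) != n) {
    stop(sprintf("configuration error: build section has %d rows for %d atoms; an equilibrium value is missing",
                 nrow(bd), n), call. = FALSE)
  }
  coords <- matrix(NA_real_, n, 3L)
  placed <- logical(n)
  for (r in seq_len(nrow(bd))) {
    a <- bd$atom[r]
    if (bd$r1[r] == 0L) {           # first atom at origin
      coords[a, ] <- c(0, 0, 0)
    } else if (bd$r2[r] == 0L) {    # second atom along -z (tail direction)
      coords[a, ] <- coords[bd$r1[r], ] + c(0, 0, -bd$length[r])
    } else if (bd$r3[r] == 0L) {    # third atom in the xz-plane
      p <- coords[bd$r1[r], ]; q <- coords[bd$r2[r], ]
      u <- unit3(q - p)
      # rotate u by the bond angle within the xz-plane
      ax <- c(0, 1, 0)
      d <- rotate_about_axis(u, c(0, 0, 0), ax, bd$angle[r])
      coords[a, ] <- p + bd$length[r] * d
    } else {
      refs <- c(bd$r1[r], bd$r2[r], bd$r3[r])
      if (any(!placed[refs])) {
        stop(sprintf("configuration error: build row for atom %d references unplaced atoms", a),
             call. = FALSE)
      }
      coords[a, ] <- place_atom(coords[refs[1L], ], coords[refs[2L], ], coords[refs[3L], ],
                                bd$length[r], bd$angle[r], bd$torsion[r])
    }
    placed[a] <- TRUE
  }
  if (any(!placed)) {
    stop("configuration error: equilibrium value missing for atom(s) ",
         paste(which(!placed), collapse = ", "), call. = FALSE)
  }
  conf <- mc_config(coords, box = NULL)
  check_bonds(conf, topology, tol = 1e-9)
  conf
}

#' Build a crystalline bilayer start configuration
#'
#' Two opposed leaflets of all-trans lipids on lattices inside a cubic cell,
#' tails pointing toward the bilayer midplane (z = 0), each lipid rotated by
#' a seed-determined uniform random angle about its own long (z) axis through
#' its center of mass, so leaflet centers of mass stay exactly
#' mirror-symmetric.
#'
#' @param topology An `mc_topology` for a single lipid.
#' @param n_per_leaflet Lipids per leaflet. Must be a perfect square for the
#'   default square lattice; otherwise supply `layout`.
#' @param lattice_spacing Nominal lattice spacing, Angstrom; the cubic cell
#'   edge is `sqrt(n_per_leaflet) * lattice_spacing`.
#' @param seed Integer seed for the random rotations.
#' @param layout Optional `c(nx, ny)` rectangular layout (e.g. `c(8, 4)` for
#'   32 lipids per leaflet inside the cubic cell).
#' @return A list with the replicated `topology` and the start `conf`
#'   (an `mc_config` with a cubic box, periodic in x and y).
#' @export
build_bilayer_start <- function(topology, n_per_leaflet, lattice_spacing = 8,
                                seed = 1L, layout = NULL) {
  stopifnot(inherits(topology, "mc_topology"))
  if (is.null(layout)) {
    s <- sqrt(n_per_leaflet)
    if (abs(s - round(s)) > 1e-9) {
      stop("n_per_leaflet is not a perfect square; pass an explicit layout, e.g. layout = c(8, 4)",
           call. = FALSE)
    }
    layout <- c(round(s), round(s))
  }
  nx <- layout[1L]; ny <- layout[2L]
  if (nx * ny != n_per_leaflet) {
    stop("layout does not match n_per_leaflet", call. = FALSE)
  }
  L <- sqrt(n_per_leaflet) * lattice_spacing
  mono <- build_monomer_start(topology)
  xyz0 <- mono$coords
  # center the template laterally on its center of mass; put the tail end at z = 2
  masses <- topology$atoms$mass
  com <- colSums(xyz0 * masses) / sum(masses)
  xyz0[, 1] <- xyz0[, 1] - com[1]
  xyz0[, 2] <- xyz0[, 2] - com[2]
  xyz0[, 3] <- xyz0[, 3] - min(xyz0[, 3]) + 2

  n_lip <- 2L * n_per_leaflet
  sys_top <- replicate_topology(topology, n_lip)
  nat <- topology$n_atoms
  coords <- matrix(0, nat * n_lip, 3L)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  angles <- stats::runif(n_lip, 0, 2 * pi)

  k <- 0L
  for (leaf in c(1L, -1L)) {
    for (iy in seq_len(ny)) {
      for (ix in seq_len(nx)) {
        k <- k + 1L
        xyz <- xyz0
        if (leaf < 0L) xyz[, 3] <- -xyz[, 3]       # lower leaflet mirrored in z
        # rotate about the molecule's own vertical axis through its lateral COM (0,0)
        xyz <- rotate_about_axis(xyz, c(0, 0, 0), c(0, 0, 1), angles[k])
        cx <- (ix - 0.5) * L / nx
        cy <- (iy - 0.5) * L / ny
        xyz[, 1] <- xyz[, 1] + cx
        xyz[, 2] <- xyz[, 2] + cy
        coords[(k - 1L) * nat + seq_len(nat), ] <- xyz
      }
    }
  }

  conf <- mc_config(coords, box = L)
  # overlap check with minimum image
  close_pair <- closest_pair(conf, min_dist = 0.5)
  if (!is.null(close_pair)) {
    stop(sprintf("bilayer build error: atoms %d and %d are %.3f Angstrom apart (< 0.5)",
                 close_pair[1], close_pair[2], close_pair[3]), call. = FALSE)
  }
  list(topology = sys_top, conf = conf)
}

# first pair of non-bonded atoms closer than min_dist (minimum image), or NULL
closest_pair <- function(conf, min_dist = 0.5) {
  x <- conf$coords
  n <- nrow(x)
  cell <- max(min_dist, 1)
  # coarse grid to keep this O(n)
  key <- floor(x / cell)
  id <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  buckets <- split(seq_len(n), id)
  for (b in buckets) {
    if (length(b) < 2L) next
    d <- as.matrix(stats::dist(x[b, , drop = FALSE]))
    diag(d) <- Inf
    w <- which(d < min_dist, arr.ind = TRUE)
    if (nrow(w)) {
      i <- b[w[1, 1]]; j <- b[w[1, 2]]
      return(c(min(i, j), max(i, j), d[w[1, 1], w[1, 2]]))
    }
  }
  NULL
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("<mc_config> %d atoms%s\n", nrow(x$coords),
              if (is.null(x$box)) ", non-periodic" else
                sprintf(", cubic box %.2f Angstrom (periodic %s)", x$box,
                        paste(c("x", "y", "z")[x$periodic], collapse = ""))))
  invisible(x)
}
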