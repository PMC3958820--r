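# Molecular topology: united atoms, the fixed-length bond tree, molecule
# membership, external atoms and their construction frames.

#' Build a topology from a parameter object or file
#'
#' Validates that the bond graph of each molecule is a connected tree (the
#' constant-bond-length approximation assumes no rings for DPPC) and compiles
#' adjacency and bond-length lookups.
#'
#' @param params An `mc_params` object or the path to a parameter file.
#' @return An object of class `mc_topology` with elements `atoms`, `bonds`,
#'   `n_atoms`, `mol` (molecule index per atom), `n_mol`, `adj` (skeleton and
#'   full adjacency lists), `external` (atom ids), `external_frames`,
#'   `main_chain` and `params` (the force-field parameters the topology was
#'   built from).
#' @export
build_topology <- function(params) {
  if (is.character(params)) params <- read_parameter_file(params)
  stopifnot(inherits(params, "mc_params"))
  atoms <- params$atoms
  bonds <- params$bonds
  n <- nrow(atoms)
  if (n == 0L) stop("topology error: no atoms", call. = FALSE)
  if (!all(sort(as.integer(atoms$id)) == seq_len(n))) {
    stop("topology error: atom ids must be 1..n", call. = FALSE)
  }
  if (nrow(bonds)) {
    bad <- bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n | bonds$i == bonds$j
    if (any(bad)) {
      stop("topology error: bond references an unknown atom (line(s) ",
           paste(which(bad), collapse = ", "), ")", call. = FALSE)
    }
  }

  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) sort(as.integer(v)))

  # connected components = molecules; each must be a tree
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- ncomp; queue <- c(queue, w) }
      }
    }
  }
  for (m in seq_len(ncomp)) {
    ids <- which(comp == m)
    nb <- sum(bonds$i %in% ids)
    if (nb != length(ids) - 1L) {
      stop(sprintf("topology error: molecule %d has %d atoms but %d bonds; bond graph must be a tree",
                   m, length(ids), nb), call. = FALSE)
    }
  }

  ext <- as.integer(params$externals$atom)
  if (length(ext)) {
    fr <- params$externals
    bonded_ok <- vapply(seq_len(nrow(fr)), function(r) fr$parent[r] %in% adj[[fr$atom[r]]], TRUE)
    if (!all(bonded_ok)) {
      stop("topology error: external atom not bonded to its frame parent", call. = FALSE)
    }
  }

  # bond length lookup, keyed "i:j" with i < j
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j), sep = ":")
  blen <- stats::setNames(bonds$length, key)

  # skeleton adjacency excludes external atoms
  skel_adj <- lapply(seq_len(n), function(i) setdiff(adj[[i]], ext))

  structure(list(
    atoms = atoms, bonds = bonds, n_atoms = n,
    mol = comp, n_mol = ncomp,
    adj = adj, skel_adj = skel_adj, blen = blen,
    external = ext, external_frames = params$externals,
    main_chain = params$main_chain,
    params = params
  ), class = "mc_topology")
}

#' Build the united-atom DPPC topology
#'
#' Reads the shipped (or a user-edited) parameter file and returns the
#' 50-site united-atom DPPC topology: a branched main chain with seven
#' external atoms (three choline N-methyls, two non-ester phosphate oxygens,
#' two carbonyl oxygens).
#'
#' @param parameter_file Path to the parameter file; defaults to the file
#'   shipped with the package.
#' @return An `mc_topology` object.
#' @export
build_dppc_topology <- function(parameter_file = dppc_parameter_file()) {
  build_topology(parameter_file)
}

#' Path to the shipped DPPC parameter file
#' @return A file path.
#' @export
dppc_parameter_file <- function() {
  system.file("extdata", "dppc_ua.prm", package = "lipidmc", mustWork = TRUE)
}

#' Path to the shipped DPPC move-plan file
#' @return A file path.
#' @export
dppc_plan_file <- function() {
  system.file("extdata", "dppc_ua.plan", package = "lipidmc", mustWork = TRUE)
}

# fixed bond length between atoms i and j (must be bonded)
bond_length <- function(topology, i, j) {
  v <- topology$blen[paste(min(i, j), max(i, j), sep = ":")]
  if (is.na(v)) stop(sprintf("atoms %d and %d are not bonded", i, j), call. = FALSE)
  unname(v)
}

#' Replicate a single-molecule system n times
#'
#' Copies atoms, bonds, energy terms and external frames with index offsets,
#' for building multi-lipid systems from the one-molecule parameter file.
#'
#' @param topology An `mc_topology` describing one molecule.
#' @param n Number of copies.
#' @return An `mc_topology` for the n-molecule system.
#' @export
replicate_topology <- function(topology, n) {
  stopifnot(inherits(topology, "mc_topology"), n >= 1)
  if (n == 1L) return(topology)
  if (topology$n_mol != 1L) stop("replicate_topology expects a one-molecule topology", call. = FALSE)
  p <- topology$params
  nat <- nrow(p$atoms)
  off <- rep((seq_len(n) - 1L) * nat, each = nat)

  rep_df <- function(df, idx_cols, times = n, nr = nrow(df)) {
    if (!nr) return(df)
    out <- df[rep(seq_len(nr), times), , drop = FALSE]
    o <- rep((seq_len(times) - 1L) * nat, each = nr)
    for (cl in idx_cols) out[[cl]] <- out[[cl]] + o
    rownames(out) <- NULL
    out
  }

  p2 <- p
  p2$atoms <- rep_df(p$atoms, "id")
  p2$bonds <- rep_df(p$bonds, c("i", "j"))
  p2$angles <- rep_df(p$angles, c("i", "j", "k"))
  p2$torsions <- rep_df(p$torsions, c("i", "j", "k", "l"))
  p2$rb <- rep_df(p$rb, c("i", "j", "k", "l"))
  p2$externals <- rep_df(p$externals, c("atom", "parent", "ref1", "ref2"))
  p2$main_chain <- unlist(lapply(seq_len(n) - 1L, function(k) {
    lapply(topology$main_chain, function(path) path + k * nat)
  }), recursive = FALSE)
  p2$build <- p$build  # build section stays per-molecule
  build_topology(p2)
}

#' @export
print.mc_topology <- function(x, ...) {
  cat(sprintf("<mc_topology> %s: %d atoms, %d bonds, %d molecule(s), %d external atom(s)\n",
              x$params$name, x$n_atoms, nrow(x$bonds), x$n_mol, length(x$external)))
  invisible(x)
}
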