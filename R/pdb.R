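# PDB interchange: united atoms as single ATOM records, one molecule per
# residue, CRYST1 for the periodic cell, CONECT for every bond. Reading goes
# through bio3d; the writer is in-package so CRYST1/CONECT are always present.

#' Write a configuration to PDB
#'
#' @param conf An `mc_config`.
#' @param topology An `mc_topology`.
#' @param path Output path.
#' @param conect Write CONECT records for all bonds.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conf, topology, path, conect = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_pdb_body(con, conf, topology, model = NULL, conect = conect)
  writeLines("END", con)
  invisible(path)
}

.write_pdb_body <- function(con, conf, topology, model = NULL, conect = TRUE) {
  if (!is.null(conf$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       conf$box, conf$box, conf$box, 90, 90, 90), con)
  }
  if (!is.null(model)) writeLines(sprintf("MODEL     %4d", model), con)
  X <- conf$coords
  at <- topology$atoms
  nat_mol <- topology$n_atoms / topology$n_mol
  lines <- sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(topology$n_atoms),
                   substr(at$name, 1, 4),
                   "DPC",
                   "A",
                   topology$mol,
                   X[, 1], X[, 2], X[, 3], 1, 0,
                   substr(at$element, 1, 2))
  writeLines(lines, con)
  if (is.null(model)) {
    if (conect) {
      b <- topology$bonds
      writeLines(sprintf("CONECT%5d%5d", b$i, b$j), con)
    }
  } else {
    writeLines("ENDMDL", con)
  }
  invisible(NULL)
}

#' Read a configuration from PDB
#'
#' Parses with `bio3d::read.pdb`; coordinates are matched to the topology by
#' record order and atom count, with a name map returned for inspection.
#'
#' @param path PDB file path.
#' @param topology An `mc_topology` the file must match.
#' @return A list: `conf` (an `mc_config`; box from CRYST1 when present) and
#'   `name_map` (data.frame of file names vs topology names).
#' @export
read_pdb <- function(path, topology) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (nrow(a) != topology$n_atoms) {
    stop(sprintf("mapping error: PDB has %d atoms, topology has %d",
                 nrow(a), topology$n_atoms), call. = FALSE)
  }
  coords <- cbind(a$x, a$y, a$z)
  box <- NULL
  hdr <- readLines(path, n = 5L, warn = FALSE)
  cr <- grep("^CRYST1", hdr, value = TRUE)
  if (length(cr)) {
    box <- as.numeric(substr(cr[1], 7, 15))
    if (!is.finite(box) || box <= 0) box <- NULL
  }
  conf <- mc_config(coords, box = box)
  list(conf = conf,
       name_map = data.frame(file = trimws(a$elety), topology = topology$atoms$name))
}

#' Write a multi-frame PDB trajectory
#'
#' One MODEL block per saved frame; CRYST1 from the first frame's box.
#'
#' @param trajectory An `mc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- trajectory$topology
  for (k in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[k]]
    conf <- structure(list(coords = fr$coords, box = fr$box,
                           periodic = c(TRUE, TRUE, FALSE)), class = "mc_config")
    .write_pdb_body(con, conf, top, model = k)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as extended XYZ
#'
#' Alternate trajectory format: per frame an atom count line, a comment line
#' carrying the cycle stamp and box edge, then `element x y z` rows.
#'
#' @inheritParams write_pdb_trajectory
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- trajectory$topology
  for (fr in trajectory$frames) {
    writeLines(sprintf("%d", top$n_atoms), con)
    writeLines(sprintf("cycle=%d box=%s", fr$cycle,
                       if (is.null(fr$box)) "NA" else sprintf("%.6f", fr$box)), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", top$atoms$element,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Write per-cycle scalars as CSV
#'
#' @param trajectory An `mc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalars <- function(trajectory, path) {
  utils::write.csv(trajectory$scalars, path, row.names = FALSE)
  invisible(path)
}
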