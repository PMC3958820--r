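# Plain-text force-field parameter files.
#
# The file is the source of truth for the molecular model: united-atom
# properties (mass, electron count, van der Waals radius, partial charge),
# the fixed bond lengths (constant-bond-length approximation), harmonic
# bond-angle terms, Fourier and Ryckaert-Bellemans torsion terms,
# Lennard-Jones types, the external-atom frames, and a z-matrix used to
# construct the all-trans start conformation from equilibrium values.
#
# Sections are introduced by a [name] line; fields are whitespace separated;
# '#' starts a comment. Angles are degrees in the file, radians in memory.

.param_sections <- c("meta", "defaults", "atoms", "bonds", "angles",
                     "torsions", "rb_torsions", "lj_types", "externals",
                     "main_chain", "build")

#' Read a force-field parameter file
#'
#' @param path Path to a plain-text parameter file.
#' @return An object of class `mc_params`: a list with elements `name`,
#'   `defaults`, `atoms`, `bonds`, `angles`, `torsions`, `rb`, `lj`,
#'   `externals`, `main_chain` and `build`. Angular quantities are stored in
#'   radians.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  current <- NA_character_
  rows <- vector("list", length(.param_sections))
  names(rows) <- .param_sections
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    if (grepl("^\\[", txt)) {
      sec <- sub("^\\[\\s*([A-Za-z_]+)\\s*\\]$", "\\1", txt)
      if (!sec %in% .param_sections) {
        stop(sprintf("parameter file parse error at line %d: unknown section '%s'", ln, sec),
             call. = FALSE)
      }
      current <- sec
      next
    }
    if (is.na(current)) {
      stop(sprintf("parameter file parse error at line %d: data before any [section]", ln),
           call. = FALSE)
    }
    rows[[current]] <- c(rows[[current]], list(list(ln = ln, tok = strsplit(txt, "\\s+")[[1]])))
  }

  tok_table <- function(sec, fields, types) {
    out <- lapply(rows[[sec]], function(r) {
      if (length(r$tok) < length(fields)) {
        stop(sprintf("parameter file parse error at line %d: section [%s] needs %d fields, got %d",
                     r$ln, sec, length(fields), length(r$tok)), call. = FALSE)
      }
      vals <- r$tok[seq_along(fields)]
      converted <- mapply(function(v, ty) {
        if (ty == "c") return(v)
        x <- suppressWarnings(as.numeric(v))
        if (is.na(x)) {
          stop(sprintf("parameter file parse error at line %d: '%s' is not numeric", r$ln, v),
               call. = FALSE)
        }
        x
      }, vals, types, SIMPLIFY = FALSE)
      names(converted) <- fields
      converted
    })
    if (!length(out)) {
      df <- as.data.frame(stats::setNames(rep(list(if (TRUE) numeric(0)), length(fields)), fields))
      for (f in seq_along(fields)) if (types[f] == "c") df[[fields[f]]] <- character(0)
      return(df)
    }
    do.call(rbind, lapply(out, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  }

  deg2rad <- pi / 180

  defaults <- list()
  for (r in rows[["defaults"]]) defaults[[r$tok[1]]] <- as.numeric(r$tok[2])
  meta <- list()
  for (r in rows[["meta"]]) meta[[r$tok[1]]] <- r$tok[2]

  atoms <- tok_table("atoms", c("id", "name", "type", "element", "mass", "electrons", "vdw", "charge"),
                     c("n", "c", "c", "c", "n", "n", "n", "n"))
  if (nrow(atoms)) {
    bad <- which(atoms$mass <= 0 | atoms$electrons < 0 | atoms$vdw <= 0)
    if (length(bad)) {
      stop("parameter file: invalid atom record for id(s) ",
           paste(atoms$id[bad], collapse = ", "),
           " (need mass > 0, electrons >= 0, vdw > 0)", call. = FALSE)
    }
  }
  bonds <- tok_table("bonds", c("i", "j", "length"), c("n", "n", "n"))
  if (nrow(bonds) && any(bonds$length <= 0)) {
    stop("parameter file: every bond must carry a fixed length > 0", call. = FALSE)
  }
  angles <- tok_table("angles", c("i", "j", "k", "k_theta", "theta0"), c("n", "n", "n", "n", "n"))
  if (nrow(angles)) angles$theta0 <- angles$theta0 * deg2rad
  torsions <- tok_table("torsions", c("i", "j", "k", "l", "v", "n", "gamma"),
                        c("n", "n", "n", "n", "n", "n", "n"))
  if (nrow(torsions)) torsions$gamma <- torsions$gamma * deg2rad
  rb <- tok_table("rb_torsions", c("i", "j", "k", "l", "c0", "c1", "c2", "c3", "c4", "c5"),
                  c("n", "n", "n", "n", "n", "n", "n", "n", "n", "n"))
  lj <- tok_table("lj_types", c("type", "rmin_half", "epsilon"), c("c", "n", "n"))
  externals <- tok_table("externals", c("atom", "parent", "ref1", "ref2"), c("n", "n", "n", "n"))
  build <- tok_table("build", c("atom", "r1", "r2", "r3", "length", "angle", "torsion"),
                     c("n", "n", "n", "n", "n", "n", "n"))
  if (nrow(build)) {
    build$angle <- build$angle * deg2rad
    build$torsion <- build$torsion * deg2rad
  }
  main_chain <- lapply(rows[["main_chain"]], function(r) as.integer(r$tok))

  structure(list(
    name = if (!is.null(meta$name)) meta$name else "unnamed",
    defaults = defaults,
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    rb = rb, lj = lj, externals = externals, main_chain = main_chain,
    build = build
  ), class = "mc_params")
}

#' Write a force-field parameter object to a file
#'
#' Deterministic inverse of [read_parameter_file()] (no timestamps).
#'
#' @param params An `mc_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path) {
  rad2deg <- 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[meta]")
  w("name %s", params$name)
  w("[defaults]")
  for (nm in names(params$defaults)) w("%s %.10g", nm, params$defaults[[nm]])
  w("[atoms]")
  a <- params$atoms
  for (r in seq_len(nrow(a))) {
    w("%d %s %s %s %.6f %g %.4f %.6f", a$id[r], a$name[r], a$type[r], a$element[r],
      a$mass[r], a$electrons[r], a$vdw[r], a$charge[r])
  }
  w("[bonds]")
  b <- params$bonds
  for (r in seq_len(nrow(b))) w("%d %d %.6f", b$i[r], b$j[r], b$length[r])
  w("[angles]")
  g <- params$angles
  for (r in seq_len(nrow(g))) {
    w("%d %d %d %.4f %.10f", g$i[r], g$j[r], g$k[r], g$k_theta[r], g$theta0[r] * rad2deg)
  }
  w("[torsions]")
  t <- params$torsions
  for (r in seq_len(nrow(t))) {
    w("%d %d %d %d %.4f %g %.4f", t$i[r], t$j[r], t$k[r], t$l[r], t$v[r], t$n[r],
      t$gamma[r] * rad2deg)
  }
  w("[rb_torsions]")
  rb <- params$rb
  for (r in seq_len(nrow(rb))) {
    w("%d %d %d %d %.6f %.6f %.6f %.6f %.6f %.6f", rb$i[r], rb$j[r], rb$k[r], rb$l[r],
      rb$c0[r], rb$c1[r], rb$c2[r], rb$c3[r], rb$c4[r], rb$c5[r])
  }
  w("[lj_types]")
  lj <- params$lj
  for (r in seq_len(nrow(lj))) w("%s %.4f %.4f", lj$type[r], lj$rmin_half[r], lj$epsilon[r])
  w("[externals]")
  e <- params$externals
  for (r in seq_len(nrow(e))) w("%d %d %d %d", e$atom[r], e$parent[r], e$ref1[r], e$ref2[r])
  w("[main_chain]")
  for (p in params$main_chain) w("%s", paste(p, collapse = " "))
  w("[build]")
  bd <- params$build
  for (r in seq_len(nrow(bd))) {
    w("%d %d %d %d %.6f %.10f %.10f", bd$atom[r], bd$r1[r], bd$r2[r], bd$r3[r],
      bd$length[r], bd$angle[r] * rad2deg, bd$torsion[r] * rad2deg)
  }
  invisible(path)
}

#' @export
print.mc_params <- function(x, ...) {
  cat(sprintf("<mc_params> %s: %d atoms, %d bonds, %d angle terms, %d torsion terms, %d RB terms\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$torsions), nrow(x$rb)))
  invisible(x)
}
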