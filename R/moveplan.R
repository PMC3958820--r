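# Move plans: the assignment of every sampled degree of freedom to a move
# class (breakage / crankshaft / torsion / bond_angle), with maximum step
# sizes. A breakage entry contributes 3 scalar DOF (the Cartesian move of the
# breakage atom); every other entry contributes 1.

#' Load a move plan
#'
#' Plan files are plain text, one DOF entry per line, '#' comments:
#' \preformatted{
#' breakage   <atom> <max_step_Angstrom>
#' crankshaft <atom> <max_angle_deg>
#' torsion    <axis_a> <axis_b> <max_angle_deg> [moved atoms...]
#' bond_angle <i> <j> <k> <max_angle_deg>
#' }
#' Torsion entries rotate, by default, the whole subtree on the `axis_b` side
#' of the bond; an explicit moved-atom list restricts the rotation (every
#' moved atom's bonds must stay inside the moved set or on the axis).
#' Bond-angle entries rotate the subtree on the `k` side about an axis
#' through `j` perpendicular to the `i-j-k` plane.
#'
#' @param plan_file Path to a plan file.
#' @param topology The `mc_topology` the plan refers to.
#' @param closure_rule See [compile_move_plan()].
#' @return An object of class `mc_moveplan`: a list with `entries` (compiled
#'   per-entry geometry) and `total_dof`.
#' @export
load_move_plan <- function(plan_file, topology, closure_rule = c("lab_angle", "anchor_angle")) {
  closure_rule <- match.arg(closure_rule)
  if (!file.exists(plan_file)) stop("plan file not found: ", plan_file, call. = FALSE)
  raw <- sub("#.*$", "", readLines(plan_file, warn = FALSE))
  entries <- list()
  for (ln in seq_along(raw)) {
    txt <- trimws(raw[ln])
    if (!nzchar(txt)) next
    tok <- strsplit(txt, "\\s+")[[1]]
    cls <- tok[1]
    num <- suppressWarnings(as.numeric(tok[-1]))
    if (any(is.na(num))) stop(sprintf("plan error at line %d: non-numeric field", ln), call. = FALSE)
    e <- switch(cls,
      breakage   = list(class = "breakage", atom = as.integer(num[1]), step = num[2]),
      crankshaft = list(class = "crankshaft", atom = as.integer(num[1]), step = num[2] * pi / 180),
      torsion    = list(class = "torsion", axis = as.integer(num[1:2]), step = num[3] * pi / 180,
                        explicit = if (length(num) > 3) as.integer(num[-(1:3)]) else NULL),
      bond_angle = list(class = "bond_angle", triple = as.integer(num[1:3]), step = num[4] * pi / 180),
      stop(sprintf("plan error at line %d: unknown move class '%s'", ln, cls), call. = FALSE)
    )
    e$line <- ln
    entries <- c(entries, list(e))
  }
  compile_move_plan(entries, topology, closure_rule = closure_rule)
}

# subtree on the `from` side when the edge (block, from) is cut
.subtree <- function(topology, block, from) {
  seen <- c(block, from)
  queue <- from
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    nxt <- setdiff(topology$adj[[v]], seen)
    seen <- c(seen, nxt)
    queue <- c(queue, nxt)
  }
  sort(out)
}

# external atoms whose frame touches `moved` but are not in it
.riders_of <- function(topology, moved) {
  fr <- topology$external_frames
  if (!nrow(fr)) return(fr[0, ])
  touch <- (fr$parent %in% moved | fr$ref1 %in% moved | fr$ref2 %in% moved) & !(fr$atom %in% moved)
  fr[touch, , drop = FALSE]
}

#' Compile a list of raw plan entries against a topology
#'
#' Normally called through [load_move_plan()]; exposed so fixtures can build
#' plans in code.
#'
#' @param entries List of raw entry lists (see [load_move_plan()] for fields).
#' @param topology An `mc_topology`.
#' @param closure_rule Closure selection rule for anchored closure atoms:
#'   `"lab_angle"` (default; unique, exactly reversible, regular at planar
#'   geometry) or `"anchor_angle"` (preserves the bond angle at the anchor;
#'   two analytic solutions chosen by proximity, but degenerate at trans
#'   torsions).
#' @return An `mc_moveplan`.
#' @export
compile_move_plan <- function(entries, topology, closure_rule = c("lab_angle", "anchor_angle")) {
  closure_rule <- match.arg(closure_rule)
  n <- topology$n_atoms
  ext <- topology$external
  compiled <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    where <- if (!is.null(e$line)) sprintf(" (plan line %d)", e$line) else ""
    chk <- function(ids) {
      if (any(ids < 1L | ids > n)) {
        stop(sprintf("plan error%s: atom index out of range 1..%d", where, n), call. = FALSE)
      }
    }
    if (e$class == "breakage") {
      b <- e$atom; chk(b)
      if (b %in% ext) {
        stop(sprintf("plan error%s: external atom %d cannot be a breakage atom; external atoms move only by internal coordinates",
                     where, b), call. = FALSE)
      }
      nbrs <- topology$skel_adj[[b]]
      if (!length(nbrs)) stop(sprintf("plan error%s: breakage atom %d has no skeleton neighbors", where, b), call. = FALSE)
      closures <- lapply(nbrs, function(cc) {
        anchors <- setdiff(topology$skel_adj[[cc]], b)
        if (length(anchors) > 1L) {
          stop(sprintf("plan error%s: closure atom %d of breakage atom %d has %d outer anchors; closure needs at most one",
                       where, cc, b, length(anchors)), call. = FALSE)
        }
        if (!length(anchors)) {
          return(list(c = cc, a = NA_integer_, an = NA_integer_, case = "translate",
                      len_cb = bond_length(topology, cc, b), len_ca = NA_real_))
        }
        a <- anchors[[1L]]
        cand <- setdiff(topology$skel_adj[[a]], c(cc, b, nbrs))
        an <- if (length(cand)) min(cand) else NA_integer_
        # default closure preserves the lab-referenced circle angle: unique,
        # exactly reversible, and regular at planar (trans) geometries where
        # the anchor-angle-preserving rule degenerates
        list(c = cc, a = a, an = an,
             case = if (closure_rule == "anchor_angle" && !is.na(an)) "anchor_angle" else "lab_angle",
             len_cb = bond_length(topology, cc, b),
             len_ca = bond_length(topology, cc, a))
      })
      closure_atoms <- vapply(closures, `[[`, 0L, "c")
      moved <- sort(c(b, closure_atoms))
      riders <- .riders_of(topology, moved)
      compiled[[k]] <- list(class = "breakage", dof = 3L, atom = b, step = e$step,
                            closures = closures, closure_atoms = closure_atoms,
                            moved = moved, riders = riders)
    } else if (e$class == "crankshaft") {
      cc <- e$atom; chk(cc)
      fl <- topology$skel_adj[[cc]]
      if (length(fl) != 2L) {
        stop(sprintf("plan error%s: crankshaft atom %d needs exactly two bonded flanking atoms, has %d",
                     where, cc, length(fl)), call. = FALSE)
      }
      riders <- .riders_of(topology, cc)
      compiled[[k]] <- list(class = "crankshaft", dof = 1L, atom = cc, step = e$step,
                            flank = fl, moved = cc, riders = riders)
    } else if (e$class == "torsion") {
      chk(e$axis)
      a <- e$axis[1L]; b <- e$axis[2L]
      if (!(b %in% topology$adj[[a]])) {
        stop(sprintf("plan error%s: torsion axis %d-%d is not a bond", where, a, b), call. = FALSE)
      }
      moved <- if (is.null(e$explicit)) setdiff(.subtree(topology, a, b), b) else sort(e$explicit)
      chk(moved)
      # the rotated set must be terminal: every bond from a moved atom stays
      # inside moved or hits the axis
      for (m in moved) {
        out <- setdiff(topology$adj[[m]], c(moved, a, b))
        if (length(out)) {
          stop(sprintf("plan error%s: rotated subtree is not terminal; atom %d is bonded to unmoved atom %d",
                       where, m, out[1L]), call. = FALSE)
        }
      }
      riders <- .riders_of(topology, moved)
      compiled[[k]] <- list(class = "torsion", dof = 1L, axis = c(a, b), step = e$step,
                            moved = moved, riders = riders)
    } else if (e$class == "bond_angle") {
      chk(e$triple)
      i <- e$triple[1L]; j <- e$triple[2L]; kk <- e$triple[3L]
      if (!(i %in% topology$adj[[j]]) || !(kk %in% topology$adj[[j]])) {
        stop(sprintf("plan error%s: %d-%d-%d is not a bonded angle", where, i, j, kk), call. = FALSE)
      }
      moved <- .subtree(topology, j, kk)
      for (m in moved) {
        out <- setdiff(topology$adj[[m]], c(moved, j))
        if (length(out)) {
          stop(sprintf("plan error%s: bond-angle subtree not terminal; atom %d bonded to unmoved atom %d",
                       where, m, out[1L]), call. = FALSE)
        }
      }
      riders <- .riders_of(topology, moved)
      compiled[[k]] <- list(class = "bond_angle", dof = 1L, triple = c(i, j, kk), step = e$step,
                            moved = moved, riders = riders)
    } else {
      stop(sprintf("plan error%s: unknown move class '%s'", where, e$class), call. = FALSE)
    }
  }
  total <- sum(vapply(compiled, `[[`, 0L, "dof"))
  structure(list(entries = compiled, total_dof = total, n_atoms = n), class = "mc_moveplan")
}

#' @export
print.mc_moveplan <- function(x, ...) {
  cls <- vapply(x$entries, `[[`, "", "class")
  cat(sprintf("<mc_moveplan> %d entries (%s), total_dof = %d\n",
              length(x$entries),
              paste(sprintf("%s: %d", names(table(cls)), table(cls)), collapse = ", "),
              x$total_dof))
  invisible(x)
}
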