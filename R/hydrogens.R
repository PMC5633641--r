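# Geometric construction of riding protons.  Hydrogens are placed from
# ideal sp3/sp2 local geometry relative to their bonded heavy atom; no
# energy term is involved at placement time (rotatable hydroxyls/amines are
# refined later by optimize_polar_hydrogens()).

xh_bond_length <- function(element) {
  switch(toupper(element), C = 1.09, N = 1.01, O = 0.96, S = 1.34, 1.05)
}

h_names_for <- function(parent, n) {
  base <- substring(parent, 2L)
  if (n == 1L) paste0("H", base)
  else paste0("H", base, seq_len(n))
}

neighbors_of <- function(sys, i) {
  b <- sys$bonds
  if (!nrow(b)) return(integer(0))
  c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
}

# Unit directions for n new substituents on atom `i` with existing unit
# neighbour directions in the rows of `u` (k x 3), hybridisation sp (2 or 3).
# `ref` is an optional unit vector fixing the torsional phase.
h_directions <- function(u, n, sp, ref = NULL) {
  k <- nrow(u)
  tet <- 109.471221 * DEG2RAD
  if (k == 0L) {
    base <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    if (n == 2L) {                       # bent (water-like)
      half <- 104.5 / 2 * DEG2RAD
      return(rbind(c(cos(half), sin(half), 0), c(cos(half), -sin(half), 0)))
    }
    return(base[seq_len(n), , drop = FALSE])
  }
  if (k == 1L) {
    a <- -u[1L, ]                          # away from the lone neighbour
    p <- if (!is.null(ref)) ref else c(1, 0, 0)
    if (abs(sum(p * a)) > 0.95) p <- c(0, 1, 0)
    e1 <- vunit(p - sum(p * a) * a)        # in-plane reference
    e2 <- vcross(a, e1)
    ang <- if (sp == 2L) 120 * DEG2RAD else tet
    # substituent at `ang` from the existing bond = (180 - ang) from a
    tilt <- pi - ang
    # torsional phase measured from the anchoring neighbour-of-neighbour:
    # phi = 0 is eclipsed, so singles go anti and triples staggered; sp2
    # pairs sit in the reference plane (cis + trans)
    phis <- if (sp == 2L && n == 2L) c(0, pi)
            else switch(as.character(n),
                        "1" = pi, "2" = c(2 * pi / 3, -2 * pi / 3),
                        "3" = c(pi / 3, pi, -pi / 3),
                        stop("cannot place ", n, " hydrogens on one centre"))
    return(t(vapply(phis, function(phi)
      cos(tilt) * a + sin(tilt) * (cos(phi) * e1 + sin(phi) * e2),
      numeric(3L))))
  }
  if (k == 2L) {
    b <- -(u[1L, ] + u[2L, ])
    if (vnorm(b) < 1e-8) b <- vcross(u[1L, ], u[2L, ])
    b <- vunit(b)
    if (n == 1L) return(matrix(b, 1L))
    p <- vunit(vcross(u[1L, ], u[2L, ]))
    half <- tet / 2
    return(rbind(cos(half) * b + sin(half) * p,
                 cos(half) * b - sin(half) * p))
  }
  # k >= 3: single hydrogen opposite the neighbour centroid
  b <- -colSums(u)
  if (vnorm(b) < 1e-8) stop("degenerate substitution pattern")
  matrix(vunit(b), 1L)
}

# Add `n` hydrogens to heavy atom `i`.  For a single existing neighbour the
# torsional phase is anchored on a neighbour-of-neighbour so that single
# hydrogens (hydroxyls) come out trans and CH3 groups staggered.
add_hydrogens_to_atom <- function(sys, i, n, sp) {
  if (n < 1L) return(sys)
  xyz <- coords(sys)
  nb <- neighbors_of(sys, i)
  u <- if (length(nb))
    t(apply(xyz[nb, , drop = FALSE], 1L, function(p) vunit(p - xyz[i, ])))
  else matrix(numeric(0), 0L, 3L)
  ref <- NULL
  if (length(nb) == 1L) {
    nnb <- setdiff(neighbors_of(sys, nb[1L]), i)
    if (length(nnb))
      ref <- vunit(xyz[nnb[1L], ] - xyz[nb[1L], ])
  }
  dirs <- h_directions(u, n, sp, ref)
  blen <- xh_bond_length(sys$atoms$element[i])
  pos <- sweep(dirs * blen, 2L, xyz[i, ], "+")
  nms <- h_names_for(sys$atoms$name[i], n)
  add_atoms(sys, sys$atoms$residue_index[i], nms, rep("H", n), pos,
            bond_to = rep(list(i), n))
}

existing_h_count <- function(sys, i) {
  nb <- neighbors_of(sys, i)
  sum(sys$atoms$element[nb] == "H")
}

# Template-driven hydrogen completion for one amino residue.
add_residue_hydrogens <- function(sys, res_i) {
  resname <- sys$residues$name[res_i]
  tpl <- residue_template(resname)
  hspec <- tpl$h
  # backbone defaults (proline has no amide H)
  if (resname != "PRO" && is.null(hspec[["N"]])) hspec$N <- c(1, 2)
  if (resname != "GLY" && is.null(hspec[["CA"]])) hspec$CA <- c(1, 3)
  for (nm in names(hspec)) {
    ix <- residue_atoms(sys, res_i)
    i <- ix[sys$atoms$name[ix] == nm]
    if (length(i) == 0L) next
    i <- i[1L]
    want <- hspec[[nm]][1L] - existing_h_count(sys, i)
    if (want > 0L)
      sys <- add_hydrogens_to_atom(sys, i, want, hspec[[nm]][2L])
  }
  sys
}

# Atoms of 5- or 6-membered rings (used to treat ring carbons/nitrogens as
# sp2 when no template applies).
ring_atoms <- function(sys) {
  b <- sys$bonds
  n <- nrow(sys$atoms)
  if (!nrow(b)) return(integer(0))
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1L]]] <- c(adj[[b[r, 1L]]], b[r, 2L])
    adj[[b[r, 2L]]] <- c(adj[[b[r, 2L]]], b[r, 1L])
  }
  out <- integer(0)
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1L]; j <- b[r, 2L]
    # BFS from i to j avoiding the direct edge, depth <= 5
    prevm <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    frontier <- i
    for (depth in 1:5) {
      nxt <- integer(0)
      for (f in frontier) for (g in adj[[f]]) {
        if (f == i && g == j) next
        if (is.na(dist[g])) {
          dist[g] <- depth; prevm[g] <- f; nxt <- c(nxt, g)
        }
      }
      frontier <- nxt
      if (!is.na(dist[j])) break
    }
    if (!is.na(dist[j]) && dist[j] <= 5L) {
      path <- j
      while (!is.na(prevm[path[1L]])) path <- c(prevm[path[1L]], path)
      out <- c(out, path)
    }
  }
  sort(unique(out))
}

#' Place missing (riding) hydrogens
#'
#' Amino residues are completed from the side-chain templates; other
#' residues fall back on element valences (C 4, N 3, O 2, S 2) with sp2
#' geometry for atoms in 5- or 6-membered rings.  Heavy atoms whose
#' environment cannot be templated are listed in the `h_report` attribute
#' and skipped.
#'
#' @param sys A `molsys` object.
#' @return The protonated system; `attr(, "h_report")` names skipped atoms.
#' @export
place_missing_hydrogens <- function(sys) {
  skipped <- character(0)
  for (res_i in seq_len(nrow(sys$residues))) {
    kind <- sys$residues$kind[res_i]
    if (kind == "amino") {
      sys <- add_residue_hydrogens(sys, res_i)
    } else if (kind == "water") {
      ix <- residue_atoms(sys, res_i)
      o <- ix[sys$atoms$element[ix] == "O"]
      if (length(o) == 1L) {
        want <- 2L - existing_h_count(sys, o)
        if (want > 0L) sys <- add_hydrogens_to_atom(sys, o, want, 3L)
      }
    } else {
      rings <- ring_atoms(sys)
      ix <- residue_atoms(sys, res_i)
      for (i in ix) {
        el <- sys$atoms$element[i]
        val <- switch(el, C = 4L, N = 3L, O = 2L, S = 2L, NA_integer_)
        if (is.na(val)) next
        sp <- if (i %in% rings && el %in% c("C", "N")) 2L else 3L
        if (sp == 2L) val <- val - 1L      # one valence consumed by the ring pi system
        want <- val - length(neighbors_of(sys, i))
        if (want > 0L) {
          res <- tryCatch(add_hydrogens_to_atom(sys, i, want, sp),
                          error = function(e) NULL)
          if (is.null(res)) skipped <- c(skipped, sys$atoms$name[i])
          else sys <- res
        }
      }
    }
  }
  attr(sys, "h_report") <- skipped
  sys
}

# Rotatable polar hydrogens: H on O/S (hydroxyl/thiol) or on an sp3 N with a
# single heavy neighbour (amine), plus water hydrogens.
rotatable_hydrogen_sites <- function(sys) {
  out <- list()
  for (i in seq_len(nrow(sys$atoms))) {
    el <- sys$atoms$element[i]
    if (!(el %in% c("O", "S", "N"))) next
    nb <- neighbors_of(sys, i)
    h <- nb[sys$atoms$element[nb] == "H"]
    heavy <- setdiff(nb, h)
    if (length(h) == 0L || length(heavy) != 1L) next
    if (el == "N" && length(h) < 2L) next   # amide NH is not rotatable
    # torsion axis heavy-parent; needs a grand-parent to define the torsion
    # (prefer a heavy one, fall back on a hydrogen e.g. in methanol)
    gp <- setdiff(neighbors_of(sys, heavy), i)
    gph <- gp[sys$atoms$element[gp] != "H"]
    if (length(gph)) gp <- gph
    if (length(gp) == 0L) next
    out[[length(out) + 1L]] <- list(h = h, parent = i, heavy = heavy,
                                    ref = gp[1L])
  }
  out
}
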