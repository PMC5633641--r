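# Rotamer enumeration and scanning, polar-hydrogen optimisation
# (hydroxyl torsions, His/Gln/Asn flips), and numeric surface areas.

#' Construct or load a rotamer library
#'
#' The built-in `three_state` source is the gauche-/gauche+/trans scheme:
#' the full Cartesian product of {-60, +60, 180} degrees over each
#' residue's rotatable chi bonds (so Ser has 3 rotamers and Lys 3^4 = 81;
#' Gly/Ala/Pro have a single empty rotamer).  A file source supplies
#' explicit entries: one line per rotamer, `RES chi1 [chi2 ...]`.
#'
#' @param source `"three_state"` or a path/text of a rotamer file.
#' @return Object of class `rotamer_library`.
#' @export
rotamer_library <- function(source = "three_state") {
  if (identical(source, "three_state"))
    return(structure(list(source = "three_state", entries = NULL),
                     class = "rotamer_library"))
  lines <- trimws(read_text_input(source))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    res <- toupper(f[1L])
    chi <- as.numeric(f[-1L])
    if (anyNA(chi)) stop("malformed rotamer line: ", ln)
    entries[[res]] <- c(entries[[res]], list(chi))
  }
  structure(list(source = "file", entries = entries),
            class = "rotamer_library")
}

#' Enumerate the rotamers of a residue type
#'
#' @param resname Three-letter code.
#' @param library A [rotamer_library()].
#' @return List of chi-angle tuples (degrees); a single empty tuple for
#'   residues without rotatable side-chain bonds.
#' @export
enumerate_rotamers <- function(resname, library = rotamer_library()) {
  resname <- toupper(resname)
  k <- n_chi(resname)          # errors on unknown codes
  if (library$source == "file") {
    e <- library$entries[[resname]]
    if (is.null(e)) stop("rotamer file has no entries for ", resname)
    return(e)
  }
  if (k == 0L) return(list(numeric(0)))
  states <- c(-60, 60, 180)
  grid <- do.call(expand.grid, rep(list(states), k))
  lapply(seq_len(nrow(grid)), function(r) as.numeric(grid[r, ]))
}

#' Apply a rotamer (chi-angle tuple) to a residue
#'
#' Side-chain torsions are set via [set_torsion()] in chi1..chin order;
#' the backbone does not move.
#'
#' @param sys A `molsys` object.
#' @param res_i Residue index.
#' @param chi Numeric chi tuple in degrees (length must match the residue).
#' @return The modified system.
#' @export
apply_rotamer <- function(sys, res_i, chi) {
  resname <- sys$residues$name[res_i]
  tpl <- residue_template(resname)
  if (length(chi) != length(tpl$chi))
    stop(sprintf("%s needs %d chi value(s), got %d", resname,
                 length(tpl$chi), length(chi)))
  ix <- residue_atoms(sys, res_i)
  nm <- sys$atoms$name[ix]
  for (k in seq_along(chi)) {
    quad <- vapply(tpl$chi[[k]], function(a) {
      j <- ix[nm == a]
      if (length(j) == 0L) stop("missing atom ", a, " for chi", k)
      j[1L]
    }, 0L)
    sys <- set_torsion(sys, quad, chi[k])
  }
  sys
}

#' Scan rotamer space of selected residues
#'
#' Exhaustively enumerates the rotamer product over up to six residues,
#' applies each combination, and scores it against the rest of the
#' structure (and the other scan residues) with pair-potential tables.
#' The best `top_k` combinations are kept (stable sort; enumeration order
#' breaks ties) and can be rescored with the force field.
#'
#' @param sys A `molsys` object with hydrogens placed.
#' @param residues Integer vector of 1..6 residue indices to scan.
#' @param library A [rotamer_library()].
#' @param tables Score tables (named by [table_key()] over `ff_type`
#'   labels); default [synthetic_score_tables()].
#' @param top_k Number of combinations to keep (default 10).
#' @param rescore Append force-field total energies for the kept
#'   combinations (requires `topo`, `params`).
#' @param topo,params,settings Force-field inputs for rescoring.
#' @param max_combinations Refusal guard on the enumeration size.
#' @return Object of class `rotamer_scan`: data.frame `ranking` with
#'   columns `rank`, `score`, `chi` (list of per-residue tuples), and
#'   optionally `rescore`; plus `n_combinations`.
#' @export
rotamer_scan <- function(sys, residues, library = rotamer_library(),
                         tables = synthetic_score_tables(),
                         top_k = 10L, rescore = FALSE,
                         topo = NULL, params = NULL,
                         settings = nonbonded_settings(),
                         max_combinations = 1e6) {
  if (length(residues) < 1L || length(residues) > 6L)
    stop("rotamer scans cover between 1 and 6 residues")
  rots <- lapply(residues, function(i)
    enumerate_rotamers(sys$residues$name[i], library))
  ncomb <- prod(vapply(rots, length, 0L))
  if (ncomb > max_combinations)
    stop(sprintf("refusing rotamer scan of %g combinations (guard %g)",
                 ncomb, max_combinations))
  scan_atoms <- unlist(lapply(residues, function(i) residue_atoms(sys, i)))
  env_atoms <- setdiff(seq_len(nrow(sys$atoms)), scan_atoms)
  idx <- rep(1L, length(residues))
  sizes <- vapply(rots, length, 0L)
  results <- vector("list", ncomb)
  combo <- 0L
  repeat {
    combo <- combo + 1L
    s2 <- sys
    for (k in seq_along(residues))
      s2 <- apply_rotamer(s2, residues[k], rots[[k]][[idx[k]]])
    xyz <- coords(s2)
    ty <- s2$atoms$ff_type
    sc <- 0
    if (length(env_atoms))
      sc <- sc + score_pose(xyz[env_atoms, , drop = FALSE],
                            xyz[scan_atoms, , drop = FALSE],
                            ty[env_atoms], ty[scan_atoms], tables)$total
    # scan-residue/scan-residue interactions (between different residues)
    if (length(residues) > 1L)
      for (a in seq_along(residues))
        for (b in seq_len(a - 1L)) {
          ia <- residue_atoms(s2, residues[a])
          ib <- residue_atoms(s2, residues[b])
          sc <- sc + score_pose(xyz[ia, , drop = FALSE],
                                xyz[ib, , drop = FALSE],
                                ty[ia], ty[ib], tables)$total
        }
    results[[combo]] <- list(idx = idx, score = sc,
                             chi = lapply(seq_along(residues), function(k)
                               rots[[k]][[idx[k]]]))
    # next index tuple
    k <- 1L
    while (k <= length(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
    }
    if (k > length(idx)) break
  }
  scores <- vapply(results, `[[`, 0, "score")
  ord <- order(scores)                  # stable: ties keep enumeration order
  keep <- ord[seq_len(min(top_k, length(ord)))]
  ranking <- data.frame(rank = seq_along(keep), score = scores[keep])
  ranking$chi <- lapply(results[keep], `[[`, "chi")
  if (rescore) {
    if (is.null(topo) || is.null(params))
      stop("rescoring needs topo and params")
    ranking$rescore <- vapply(seq_along(keep), function(r) {
      s2 <- sys
      for (k in seq_along(residues))
        s2 <- apply_rotamer(s2, residues[k], ranking$chi[[r]][[k]])
      energy_and_gradient(s2, topo, params, settings)$energy$total
    }, 0)
  }
  structure(list(ranking = ranking, n_combinations = ncomb,
                 residues = residues),
            class = "rotamer_scan")
}

#' @export
print.rotamer_scan <- function(x, ...) {
  cat(sprintf("<rotamer_scan> %d combinations over %d residue(s); top %d kept\n",
              x$n_combinations, length(x$residues), nrow(x$ranking)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Polar-hydrogen optimisation.

# Rotate the hydrogens of one rotatable site to torsion `ang` (degrees).
set_site_torsion <- function(sys, site, ang) {
  quad <- c(site$ref, site$heavy, site$parent, site$h[1L])
  set_torsion(sys, quad, ang)
}

ff_total <- function(sys, topo, params, settings) {
  energy_and_gradient(sys, topo, params, settings)$energy$total
}

# Histidine protonation variants: HID (delta), HIE (epsilon), HIP (both).
# Built by stripping the ring N-hydrogens and re-adding them on the target
# nitrogen(s); the residue's `variant` field records the tautomer.
his_variants <- function(sys, res_i) {
  strip <- function(s) {
    ix <- residue_atoms(s, res_i)
    hs <- ix[s$atoms$name[ix] %in% c("HD1", "HE2")]
    if (length(hs)) remove_atoms(s, hs) else s
  }
  protonate <- function(s, nname) {
    ix <- residue_atoms(s, res_i)
    i <- ix[s$atoms$name[ix] == nname][1L]
    add_hydrogens_to_atom(s, i, 1L, 2L)
  }
  base <- strip(sys)
  out <- list(
    HID = protonate(base, "ND1"),
    HIE = protonate(base, "NE2"),
    HIP = protonate(protonate(base, "ND1"), "NE2"))
  for (v in names(out)) out[[v]]$residues$variant[res_i] <- v
  out
}

# 180-degree rotation of the terminal amide/imidazole group about the
# last chi axis: swaps the O/N (or N/C) terminal positions.
flip_residue <- function(sys, res_i) {
  resname <- sys$residues$name[res_i]
  tpl <- residue_template(resname)
  k <- length(tpl$chi)
  if (k == 0L) stop("residue ", resname, " has no flip axis")
  ix <- residue_atoms(sys, res_i)
  nm <- sys$atoms$name[ix]
  quad <- vapply(tpl$chi[[k]], function(a) ix[nm == a][1L], 0L)
  xyz <- coords(sys)
  cur <- measure_dihedral(xyz[quad[1L], ], xyz[quad[2L], ],
                          xyz[quad[3L], ], xyz[quad[4L], ])
  set_torsion(sys, quad, wrap_angle(cur + 180))
}

#' Optimise polar hydrogen orientations and side-chain flips
#'
#' Hydroxyl/thiol/amine torsions (Ser, Thr, Tyr, Cys, Lys, waters) are
#' grid-searched (default 10 degree steps) on the force-field energy;
#' His, Gln and Asn are evaluated in the unflipped and flipped (180-degree
#' terminal-group rotation) states, His additionally over the delta/epsilon
#' protonation variants.  The minimal-energy state is chosen per site and
#' the site sweep is iterated to convergence.
#'
#' @param sys A `molsys` object with hydrogens present.
#' @param topo,params,settings Force-field inputs (re-perceived topology is
#'   computed internally after any His variant change).
#' @param grid_step Torsion grid step in degrees.
#' @param max_sweeps Maximum site sweeps.
#' @return List: `system` (optimised), `decisions` (data.frame of sites:
#'   residue, type, chosen, delta_e, degenerate).
#' @export
optimize_polar_hydrogens <- function(sys, topo, params,
                                     settings = nonbonded_settings(),
                                     grid_step = 10, max_sweeps = 10L) {
  decisions <- list()
  changed <- TRUE
  sweep_n <- 0L
  while (changed && sweep_n < max_sweeps) {
    changed <- FALSE
    sweep_n <- sweep_n + 1L
    decisions <- list()
    # hydroxyl / amine torsions
    for (site in rotatable_hydrogen_sites(sys)) {
      angs <- seq(-180 + grid_step, 180, by = grid_step)
      e <- vapply(angs, function(a)
        ff_total(set_site_torsion(sys, site, a), topo, params, settings), 0)
      xyz <- coords(sys)
      cur <- measure_dihedral(xyz[site$ref, ], xyz[site$heavy, ],
                              xyz[site$parent, ], xyz[site$h[1L], ])
      e_cur <- ff_total(sys, topo, params, settings)
      best <- which.min(e)
      degenerate <- diff(range(e)) < 1e-6
      if (!degenerate && e[best] < e_cur - 1e-9) {
        sys <- set_site_torsion(sys, site, angs[best])
        changed <- TRUE
      }
      decisions[[length(decisions) + 1L]] <- data.frame(
        residue = sys$atoms$residue_index[site$parent], type = "torsion",
        chosen = if (!degenerate && e[best] < e_cur - 1e-9)
          angs[best] else cur,
        delta_e = e_cur - min(e), degenerate = degenerate)
    }
    # His protonation variants (delta / epsilon / doubly protonated);
    # epsilon is the default on degenerate energies
    for (res_i in which(sys$residues$name == "HIS")) {
      cand <- his_variants(sys, res_i)
      e <- vapply(cand, function(s)
        ff_total(s, perceive_topology(s), params, settings), 0)
      degenerate <- diff(range(e)) < 1e-6
      cur_var <- sys$residues$variant[res_i]
      if (!nzchar(cur_var)) cur_var <- "HIE"
      pick <- if (degenerate) match(cur_var, names(cand), nomatch = 1L)
              else which.min(e)
      if (names(cand)[pick] != cur_var) {
        sys <- cand[[pick]]
        topo <- perceive_topology(sys)
        changed <- TRUE
      }
      decisions[[length(decisions) + 1L]] <- data.frame(
        residue = res_i, type = "his_variant",
        chosen = names(cand)[pick], delta_e = diff(range(e)),
        degenerate = degenerate)
    }
    # flips
    for (res_i in which(sys$residues$name %in% c("HIS", "GLN", "ASN"))) {
      e0 <- ff_total(sys, topo, params, settings)
      flipped <- flip_residue(sys, res_i)
      e1 <- ff_total(flipped, topo, params, settings)
      de <- e0 - e1
      degenerate <- abs(de) < 1e-6
      if (!degenerate && e1 < e0) {
        sys <- flipped
        changed <- TRUE
        chosen <- "flipped"
      } else chosen <- "unflipped"       # ties keep the input state
      decisions[[length(decisions) + 1L]] <- data.frame(
        residue = res_i, type = paste0(tolower(sys$residues$name[res_i]),
                                       "_flip"),
        chosen = chosen, delta_e = de, degenerate = degenerate)
    }
  }
  list(system = sys,
       decisions = if (length(decisions)) do.call(rbind, decisions)
       else data.frame())
}

# ---------------------------------------------------------------------------
# Surface areas (Shrake-Rupley sphere sampling).

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param sys A `molsys` object.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom sphere (default 960).
#' @return Numeric vector of per-atom accessible areas (A^2); the total is
#'   `sum()` of it.
#' @export
sasa <- function(sys, probe = 1.4, n_points = 960L) {
  xyz <- coords(sys)
  n <- nrow(xyz)
  rad <- element_vdw_radius(sys$atoms$element) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in neigh) {
      dj <- sweep(p, 2L, xyz[j, ])
      acc <- acc & (rowSums(dj * dj) > rad[j]^2)
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  out
}

#' Polar surface area
#'
#' The summed accessible area of nitrogen and oxygen atoms plus hydrogens
#' bonded to them.
#'
#' @inheritParams sasa
#' @return PSA in A^2.
#' @export
polar_surface_area <- function(sys, probe = 1.4, n_points = 960L) {
  areas <- sasa(sys, probe, n_points)
  el <- sys$atoms$element
  polar <- el %in% c("N", "O")
  for (i in which(el == "H")) {
    nb <- neighbors_of(sys, i)
    if (any(el[nb] %in% c("N", "O"))) polar[i] <- TRUE
  }
  sum(areas[polar])
}
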