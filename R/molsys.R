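#' Construct a molecular system
#'
#' The shared container all engines operate on: an atom table, residue
#' segmentation, a bond list, charge groups and an optional periodic box.
#'
#' @param atoms `data.frame` with columns `serial`, `name`, `element`,
#'   `ff_type`, `charge`, `x`, `y`, `z`, `residue_index`.
#' @param residues `data.frame` with columns `name`, `chain`, `seqnum`,
#'   `icode`, `kind`, `variant`.  When `NULL` a single ligand residue is
#'   created spanning all atoms.
#' @param bonds Integer matrix with two columns (atom indices, unordered
#'   pairs); zero rows allowed.
#' @param charge_groups List of integer vectors partitioning the atoms;
#'   defaults to one group per residue.
#' @param box Optional numeric(3): orthorhombic periodic box lengths
#'   (Angstrom).
#' @param neutralised Logical: are the charge groups asserted to sum to
#'   integer charges?
#' @return An object of class `molsys`.
#' @export
molecular_system <- function(atoms, residues = NULL, bonds = NULL,
                             charge_groups = NULL, box = NULL,
                             neutralised = FALSE) {
  need <- c("serial", "name", "element", "ff_type", "charge",
            "x", "y", "z", "residue_index")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty input: a system needs at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  if (!all(is_known_element(atoms$element)))
    stop("unknown element(s): ",
         paste(unique(atoms$element[!is_known_element(atoms$element)]),
               collapse = ", "))
  if (is.null(residues)) {
    residues <- data.frame(name = "LIG", chain = "A", seqnum = 1L,
                           icode = "", kind = "ligand", variant = "",
                           stringsAsFactors = FALSE)
    atoms$residue_index <- 1L
  }
  if (!"variant" %in% names(residues)) residues$variant <- ""
  if (!"icode" %in% names(residues)) residues$icode <- ""
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- normalize_bonds(bonds, nrow(atoms))
  if (is.null(charge_groups))
    charge_groups <- split(seq_len(nrow(atoms)), atoms$residue_index)
  cg <- sort(unlist(charge_groups, use.names = FALSE))
  if (!identical(as.integer(cg), seq_len(nrow(atoms))))
    stop("charge_groups must partition the atom set exactly")
  if (neutralised) {
    sums <- vapply(charge_groups, function(ix) sum(atoms$charge[ix]), 0)
    if (any(abs(sums - round(sums)) > 1e-6))
      stop("neutralised charge groups must sum to integers")
  }
  structure(list(atoms = atoms, residues = residues, bonds = bonds,
                 charge_groups = unname(charge_groups), box = box,
                 neutralised = neutralised),
            class = "molsys")
}

normalize_bonds <- function(bonds, natoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > natoms)) stop("bond index out of range")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bond not allowed")
    bonds <- t(apply(bonds, 1L, sort))
    bonds <- unique(bonds)
  }
  bonds
}

#' @export
print.molsys <- function(x, ...) {
  cat(sprintf("<molsys> %d atoms, %d residues, %d bonds%s\n",
              nrow(x$atoms), nrow(x$residues), nrow(x$bonds),
              if (!is.null(x$box)) sprintf(", box %.2f x %.2f x %.2f A",
                                           x$box[1], x$box[2], x$box[3])
              else ""))
  invisible(x)
}

#' Atomic coordinates of a system
#' @param sys A `molsys` object.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(sys) {
  m <- as.matrix(sys$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atomic coordinates
#' @param sys A `molsys` object.
#' @param value N x 3 numeric matrix.
#' @return The updated system.
#' @export
`coords<-` <- function(sys, value) {
  stopifnot(nrow(value) == nrow(sys$atoms), ncol(value) == 3L)
  sys$atoms$x <- value[, 1L]
  sys$atoms$y <- value[, 2L]
  sys$atoms$z <- value[, 3L]
  sys
}

#' Atom indices of one residue
#' @param sys A `molsys` object.
#' @param i Residue index.
#' @return Integer vector of atom indices.
#' @export
residue_atoms <- function(sys, i) which(sys$atoms$residue_index == i)

.amino_names <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
.water_names <- c("HOH", "WAT")

classify_residue <- function(name, het) {
  if (name %in% .water_names) return("water")
  if (name %in% .amino_names) return("amino")
  if (het) return("ligand")
  "other"
}

# ---------------------------------------------------------------------------
# PDB I/O.  Fixed-column ATOM/HETATM/TER/CONECT/CRYST1 subset.

parse_pdb_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("malformed PDB record at line %d: bad %s field '%s'",
                 lineno, what, trimws(s)))
  v
}

#' Read a PDB-format string or file
#'
#' Parses ATOM/HETATM/CONECT/CRYST1 records.  Residues are segmented by
#' (chain, sequence number, insertion code).  Alternate locations are
#' resolved by keeping the highest-occupancy record (ties: first seen).
#' CONECT records become bonds; remaining bonds are perceived by distance
#' (1.3 x covalent-radius sum, hydrogens limited to one bond).
#'
#' @param text A character scalar holding PDB text, or a path to a file.
#' @return A [molecular_system()] with an optional `cell` element from
#'   CRYST1.
#' @export
read_pdb <- function(text) {
  lines <- read_text_input(text)
  recs <- list(); conect <- list(); cell <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    tag <- toupper(substr(ln, 1L, 6L))
    if (tag == "ATOM  " || tag == "HETATM") {
      if (nchar(ln) < 54)
        stop(sprintf("malformed PDB record at line %d: shorter than 54 columns", k))
      occ <- if (nchar(ln) >= 60 && nzchar(trimws(substr(ln, 55L, 60L))))
        parse_pdb_num(substr(ln, 55L, 60L), k, "occupancy") else 1.0
      el <- if (nchar(ln) >= 78) trimws(substr(ln, 77L, 78L)) else ""
      recs[[length(recs) + 1L]] <- list(
        het = tag == "HETATM",
        serial = as.integer(parse_pdb_num(substr(ln, 7L, 11L), k, "serial")),
        name = trimws(substr(ln, 13L, 16L)),
        altloc = substr(ln, 17L, 17L),
        resname = trimws(substr(ln, 18L, 20L)),
        chain = substr(ln, 22L, 22L),
        seqnum = as.integer(parse_pdb_num(substr(ln, 23L, 26L), k, "residue number")),
        icode = trimws(substr(ln, 27L, 27L)),
        x = parse_pdb_num(substr(ln, 31L, 38L), k, "x"),
        y = parse_pdb_num(substr(ln, 39L, 46L), k, "y"),
        z = parse_pdb_num(substr(ln, 47L, 54L), k, "z"),
        occ = occ, element = el)
    } else if (tag == "CONECT") {
      f <- as.integer(substring(ln, c(7L, 12L, 17L, 22L, 27L),
                                c(11L, 16L, 21L, 26L, 31L)))
      f <- f[!is.na(f)]
      if (length(f) >= 2L)
        for (j in f[-1L]) conect[[length(conect) + 1L]] <- c(f[1L], j)
    } else if (tag == "CRYST1") {
      cell <- unit_cell(parse_pdb_num(substr(ln, 7L, 15L), k, "a"),
                        parse_pdb_num(substr(ln, 16L, 24L), k, "b"),
                        parse_pdb_num(substr(ln, 25L, 33L), k, "c"),
                        parse_pdb_num(substr(ln, 34L, 40L), k, "alpha"),
                        parse_pdb_num(substr(ln, 41L, 47L), k, "beta"),
                        parse_pdb_num(substr(ln, 48L, 54L), k, "gamma"))
    }
  }
  if (length(recs) == 0L) stop("empty input: no ATOM or HETATM records")

  # Resolve altlocs: keep the highest-occupancy record per atom site.
  key <- vapply(recs, function(r)
    paste(r$chain, r$seqnum, r$icode, r$name, sep = "|"), character(1L))
  keep <- rep(TRUE, length(recs))
  for (k in unique(key[duplicated(key)])) {
    ix <- which(key == k)
    occ <- vapply(recs[ix], `[[`, 0, "occ")
    keep[ix] <- FALSE
    keep[ix[which.max(occ)]] <- TRUE   # which.max keeps the first on ties
  }
  recs <- recs[keep]

  rkey <- vapply(recs, function(r)
    paste(r$chain, r$seqnum, r$icode, sep = "|"), character(1L))
  rix <- match(rkey, unique(rkey))
  first <- recs[!duplicated(rkey)]
  residues <- data.frame(
    name = vapply(first, `[[`, "", "resname"),
    chain = vapply(first, `[[`, "", "chain"),
    seqnum = vapply(first, function(r) r$seqnum, 0L),
    icode = vapply(first, `[[`, "", "icode"),
    kind = vapply(first, function(r) classify_residue(r$resname, r$het), ""),
    variant = "",
    stringsAsFactors = FALSE)

  element <- vapply(recs, `[[`, "", "element")
  bad <- !nzchar(element) | !is_known_element(element)
  if (any(bad))
    element[bad] <- guess_element(vapply(recs[bad], `[[`, "", "name"))
  element <- toupper(element)

  atoms <- data.frame(
    serial = vapply(recs, function(r) r$serial, 0L),
    name = vapply(recs, `[[`, "", "name"),
    element = element,
    ff_type = element,
    charge = 0,
    x = vapply(recs, function(r) r$x, 0),
    y = vapply(recs, function(r) r$y, 0),
    z = vapply(recs, function(r) r$z, 0),
    residue_index = rix,
    stringsAsFactors = FALSE)

  bonds <- matrix(integer(0), ncol = 2L)
  if (length(conect)) {
    serials <- atoms$serial
    cb <- do.call(rbind, conect)
    i <- match(cb[, 1L], serials)
    j <- match(cb[, 2L], serials)
    ok <- !is.na(i) & !is.na(j) & i != j
    bonds <- cbind(i[ok], j[ok])
  }
  sys <- molecular_system(atoms, residues, bonds)
  sys$bonds <- normalize_bonds(rbind(sys$bonds, perceive_bonds(sys)),
                               nrow(atoms))
  sys$cell <- cell
  sys
}

read_text_input <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
}

#' Perceive covalent bonds from interatomic distances
#'
#' A bond is assigned when the distance is below 1.3 x the covalent-radius
#' sum; hydrogens are limited to their single nearest neighbour.
#'
#' @param sys A `molsys` object.
#' @return Integer matrix of bonded index pairs.
#' @export
perceive_bonds <- function(sys) {
  xyz <- coords(sys)
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  rc <- element_covalent_radius(sys$atoms$element)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") * 1.3
  cand <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  cand <- cand[d[cand] > 0.4, , drop = FALSE]   # reject fused positions
  if (nrow(cand) == 0L) return(matrix(integer(0), ncol = 2L))
  # hydrogens: keep only the shortest bond per H
  isH <- sys$atoms$element == "H"
  keep <- rep(TRUE, nrow(cand))
  for (h in which(isH)) {
    ix <- which(cand[, 1L] == h | cand[, 2L] == h)
    if (length(ix) > 1L) {
      keep[ix] <- FALSE
      keep[ix[which.min(d[cand[ix, , drop = FALSE]])]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  storage.mode(cand) <- "integer"
  unname(cand)
}

#' Write a system as PDB-format text
#'
#' @param sys A `molsys` object.
#' @param conect Write CONECT records for all bonds (default TRUE).
#' @return A character scalar of PDB text.
#' @export
write_pdb <- function(sys, conect = TRUE) {
  if (nrow(sys$atoms) == 0L) stop("empty system")
  xyz <- coords(sys)
  if (any(abs(xyz) >= 10000))
    stop("coordinate overflow: |coordinate| >= 10000 A does not fit PDB columns")
  out <- character(0)
  if (!is.null(sys$cell))
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          sys$cell$a, sys$cell$b, sys$cell$c,
                          sys$cell$alpha, sys$cell$beta, sys$cell$gamma))
  at <- sys$atoms
  res <- sys$residues
  for (i in seq_len(nrow(at))) {
    r <- res[at$residue_index[i], ]
    tag <- if (r$kind %in% c("amino", "other")) "ATOM  " else "HETATM"
    nm <- at$name[i]
    # element-aligned atom-name column convention
    nm_fmt <- if (nchar(nm) >= 4L) substr(nm, 1L, 4L)
              else if (nchar(at$element[i]) == 2L) sprintf("%-4s", nm)
              else sprintf(" %-3s", nm)
    out <- c(out, sprintf("%s%5d %s %-3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                          tag, at$serial[i] %% 100000L, nm_fmt, r$name,
                          substr(paste0(r$chain, " "), 1L, 1L),
                          r$seqnum %% 10000L, substr(paste0(r$icode, " "), 1L, 1L),
                          at$x[i], at$y[i], at$z[i], 1.0, 0.0,
                          toupper(at$element[i])))
  }
  out <- c(out, "TER")
  if (conect && nrow(sys$bonds)) {
    serial <- at$serial
    adj <- split(c(sys$bonds[, 2L], sys$bonds[, 1L]),
                 c(sys$bonds[, 1L], sys$bonds[, 2L]))
    for (i in sort(as.integer(names(adj)))) {
      nb <- sort(adj[[as.character(i)]])
      for (chunk in split(nb, ceiling(seq_along(nb) / 4L)))
        out <- c(out, paste0("CONECT",
                             paste(sprintf("%5d", c(serial[i], serial[chunk])),
                                   collapse = "")))
    }
  }
  out <- c(out, "END")
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# XYZ I/O.

#' Read XYZ-format text
#' @param text Character scalar of XYZ text or a file path.
#' @return A `molsys` with one ligand residue and distance-perceived bonds.
#' @export
read_xyz <- function(text) {
  lines <- read_text_input(text)
  if (length(lines) < 1L || !nzchar(trimws(lines[[1L]])))
    stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n)) stop("XYZ parse error: first line must be the atom count")
  if (length(lines) < n + 2L)
    stop(sprintf("XYZ count mismatch: header says %d atoms, found %d",
                 n, max(0L, length(lines) - 2L)))
  rows <- strsplit(trimws(lines[3:(n + 2L)]), "[[:space:]]+")
  bad <- which(vapply(rows, length, 0L) < 4L)
  if (length(bad))
    stop(sprintf("XYZ parse error at line %d: need 'element x y z'", bad[1L] + 2L))
  el <- toupper(vapply(rows, `[[`, "", 1L))
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
  if (any(is.na(xyz))) stop("XYZ parse error: non-numeric coordinate")
  atoms <- data.frame(serial = seq_len(n), name = el, element = el,
                      ff_type = el, charge = 0,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      residue_index = 1L, stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  sys$bonds <- perceive_bonds(sys)
  sys
}

#' Write XYZ-format text
#' @param sys A `molsys` object.
#' @param comment Comment line (default empty).
#' @return Character scalar of XYZ text.
#' @export
write_xyz <- function(sys, comment = "") {
  at <- sys$atoms
  body <- sprintf("%-2s %14.6f %14.6f %14.6f", at$element, at$x, at$y, at$z)
  paste0(paste(c(nrow(at), comment, body), collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# Topology perception.

#' Perceive bonded topology from the bond graph
#'
#' Enumerates angles (all bonded paths i-j-k), proper torsions (paths
#' i-j-k-l), and the 1-2/1-3 exclusion and 1-4 scaled pair sets from graph
#' distances.
#'
#' @param sys A `molsys` object with bonds.
#' @return A list of class `topology` with elements `bonds`, `angles`,
#'   `torsions`, `impropers`, `excl12`, `excl13`, `scaled14` (index
#'   matrices).
#' @export
perceive_topology <- function(sys) {
  n <- nrow(sys$atoms)
  bonds <- sys$bonds
  adj <- vector("list", n)
  if (nrow(bonds))
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1L]; j <- bonds[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  angles <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      for (c1 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1L, c1], j, cmb[2L, c1])
    }
  }
  torsions <- list()
  if (nrow(bonds))
    for (r in seq_len(nrow(bonds))) {
      j <- bonds[r, 1L]; k <- bonds[r, 2L]
      for (i in setdiff(adj[[j]], k))
        for (l in setdiff(adj[[k]], j))
          if (i != l)
            torsions[[length(torsions) + 1L]] <- c(i, j, k, l)
    }
  to_mat <- function(lst, w) {
    if (length(lst) == 0L) return(matrix(integer(0), ncol = w))
    m <- do.call(rbind, lst)
    storage.mode(m) <- "integer"
    # canonical orientation + dedupe
    flip <- m[, 1L] > m[, w]
    m[flip, ] <- m[flip, w:1L, drop = FALSE]
    unique(m)
  }
  ang <- to_mat(angles, 3L)
  tor <- to_mat(torsions, 4L)
  # graph distances up to 3 via BFS from each atom
  pairs12 <- bonds
  p13 <- list(); p14 <- list()
  gd <- function(start) {
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    frontier <- start
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0L) break
      dist[nxt] <- depth
      frontier <- nxt
    }
    dist
  }
  for (i in seq_len(n)) {
    dist <- gd(i)
    for (j in which(dist == 2L)) if (j > i) p13[[length(p13) + 1L]] <- c(i, j)
    for (j in which(dist == 3L)) if (j > i) p14[[length(p14) + 1L]] <- c(i, j)
  }
  structure(list(bonds = bonds, angles = ang, torsions = tor,
                 impropers = matrix(integer(0), ncol = 4L),
                 excl12 = pairs12, excl13 = to_mat(p13, 2L),
                 scaled14 = to_mat(p14, 2L)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d bonds, %d angles, %d torsions, %d impropers\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              nrow(x$impropers)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# System editing helpers.

#' Remove atoms from a system
#' @param sys A `molsys` object.
#' @param idx Integer vector of atom indices to drop.
#' @return The reduced system (residues with no atoms left are dropped).
#' @export
remove_atoms <- function(sys, idx) {
  if (length(idx) == 0L) return(sys)
  n <- nrow(sys$atoms)
  keep <- setdiff(seq_len(n), idx)
  if (length(keep) == 0L) stop("cannot remove every atom")
  map <- integer(n)
  map[keep] <- seq_along(keep)
  atoms <- sys$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- sys$bonds
  if (nrow(b)) {
    ok <- b[, 1L] %in% keep & b[, 2L] %in% keep
    b <- matrix(map[b[ok, , drop = FALSE]], ncol = 2L)
  }
  # drop empty residues, remap residue indices
  used <- sort(unique(atoms$residue_index))
  rmap <- integer(nrow(sys$residues))
  rmap[used] <- seq_along(used)
  atoms$residue_index <- rmap[atoms$residue_index]
  residues <- sys$residues[used, , drop = FALSE]
  rownames(residues) <- NULL
  cg <- lapply(sys$charge_groups, function(g) map[intersect(g, keep)])
  cg <- cg[vapply(cg, length, 0L) > 0L]
  molecular_system(atoms, residues, b, cg, sys$box, FALSE)
}

#' Add atoms to an existing residue
#' @param sys A `molsys` object.
#' @param res_i Residue index receiving the atoms.
#' @param name,element Character vectors for the new atoms.
#' @param xyz Matrix (k x 3) of coordinates.
#' @param bond_to List of integer vectors: existing/new atom indices each new
#'   atom bonds to (new atoms are numbered after the current ones).
#' @return The extended system.
#' @export
add_atoms <- function(sys, res_i, name, element, xyz, bond_to = NULL) {
  k <- length(name)
  xyz <- matrix(xyz, ncol = 3L)
  n0 <- nrow(sys$atoms)
  new <- data.frame(serial = max(sys$atoms$serial) + seq_len(k),
                    name = name, element = toupper(element),
                    ff_type = toupper(element), charge = 0,
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    residue_index = res_i, stringsAsFactors = FALSE)
  atoms <- rbind(sys$atoms, new)
  bonds <- sys$bonds
  if (!is.null(bond_to))
    for (a in seq_len(k))
      for (b in bond_to[[a]])
        bonds <- rbind(bonds, c(n0 + a, b))
  cg <- sys$charge_groups
  # new atoms join the charge group of their residue's first atom
  host <- which(vapply(cg, function(g)
    any(sys$atoms$residue_index[g] == res_i), TRUE))[1L]
  if (is.na(host)) cg[[length(cg) + 1L]] <- n0 + seq_len(k)
  else cg[[host]] <- c(cg[[host]], n0 + seq_len(k))
  molecular_system(atoms, sys$residues, bonds, cg, sys$box, FALSE)
}
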