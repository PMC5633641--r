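# Z-matrix internal coordinates: construction, conversion to/from Cartesian,
# torsion editing and Ramachandran classification.
#
# Placement convention: atom 1 at the origin, atom 2 on the +x axis, atom 3
# in the xy half-plane with positive y.  Angles in degrees at this interface.

#' Construct a Z-matrix
#'
#' @param rows `data.frame` with columns `element`, `bond_ref`, `angle_ref`,
#'   `dihedral_ref` (integer indices of previously defined rows, `NA` where
#'   not applicable), `bond` (Angstrom), `angle`, `dihedral` (degrees).
#' @return Object of class `zmatrix`.
#' @export
zmatrix <- function(rows) {
  need <- c("element", "bond_ref", "angle_ref", "dihedral_ref",
            "bond", "angle", "dihedral")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("zmatrix rows lack column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(rows)
  if (n < 1L) stop("a Z-matrix needs at least one row")
  for (k in seq_len(n)) {
    refs <- c(rows$bond_ref[k], rows$angle_ref[k], rows$dihedral_ref[k])
    nref <- sum(!is.na(refs))
    want <- min(k - 1L, 3L)
    if (nref != want)
      stop(sprintf("row %d must reference exactly %d previous atom(s)", k, want))
    if (any(refs[!is.na(refs)] >= k) || any(refs[!is.na(refs)] < 1L))
      stop(sprintf("row %d references an atom not yet defined", k))
    if (anyDuplicated(c(k, refs[!is.na(refs)])))
      stop(sprintf("row %d has duplicate references", k))
  }
  structure(list(rows = rows), class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("<zmatrix> %d rows\n", nrow(x$rows)))
  invisible(x)
}

# Place atom X with |X-C| = r, angle(X,C,B) = theta and dihedral
# X-C-B-A = phi (degrees), the NeRF construction.
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * DEG2RAD
  ph <- phi * DEG2RAD
  bc <- vunit(C - B)
  n <- vcross(B - A, bc)
  if (vnorm(n) < 1e-10)
    stop("degenerate geometry: dihedral references are collinear")
  n <- vunit(n)
  m <- vcross(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Convert a Z-matrix to Cartesian coordinates
#'
#' @param z A [zmatrix()].
#' @return N x 3 matrix of coordinates (Angstrom); atom 1 at the origin,
#'   atom 2 on +x, atom 3 in the +y half of the xy plane.
#' @export
zmatrix_to_cartesian <- function(z) {
  rows <- z$rows
  n <- nrow(rows)
  xyz <- matrix(0, n, 3L)
  if (n >= 2L) xyz[2L, ] <- c(rows$bond[2L], 0, 0)
  if (n >= 3L) {
    b <- xyz[rows$bond_ref[3L], ]
    a <- xyz[rows$angle_ref[3L], ]
    th <- rows$angle[3L]
    if (th <= 1e-9 || th >= 180 - 1e-9)
      stop("degenerate geometry: bond angle of 0 or 180 degrees")
    u <- vunit(a - b)
    th <- th * DEG2RAD
    # u is +-x; the +y sine component keeps atom 3 in the upper half plane
    xyz[3L, ] <- b + rows$bond[3L] * (cos(th) * u + sin(th) * c(0, 1, 0))
  }
  if (n >= 4L)
    for (k in 4:n) {
      th <- rows$angle[k]
      if (th <= 1e-9 || th >= 180 - 1e-9)
        stop("degenerate geometry: bond angle of 0 or 180 degrees with a dependent dihedral")
      xyz[k, ] <- place_atom(xyz[rows$dihedral_ref[k], ],
                             xyz[rows$angle_ref[k], ],
                             xyz[rows$bond_ref[k], ],
                             rows$bond[k], th, rows$dihedral[k])
    }
  xyz
}

#' Convert Cartesian coordinates to a Z-matrix
#'
#' References for each row are chosen as the nearest previously defined
#' atoms that give non-degenerate angles.
#'
#' @param sys A `molsys` object.
#' @param order Optional integer permutation giving the Z-matrix atom order
#'   (default: input order).
#' @return A [zmatrix()] whose reconstruction reproduces the input geometry
#'   up to rigid motion.
#' @export
cartesian_to_zmatrix <- function(sys, order = seq_len(nrow(sys$atoms))) {
  xyz <- coords(sys)[order, , drop = FALSE]
  el <- sys$atoms$element[order]
  n <- nrow(xyz)
  if (n < 1L) stop("need at least one atom")
  rows <- data.frame(element = el, bond_ref = NA_integer_,
                     angle_ref = NA_integer_, dihedral_ref = NA_integer_,
                     bond = NA_real_, angle = NA_real_, dihedral = NA_real_,
                     stringsAsFactors = FALSE)
  ok_angle <- function(a, b, c) {
    ang <- measure_angle(a, b, c)
    ang > 1e-6 && ang < 180 - 1e-6
  }
  for (k in seq_len(n)) {
    if (k == 1L) next
    prev <- seq_len(k - 1L)
    d <- sqrt(colSums((t(xyz[prev, , drop = FALSE]) - xyz[k, ])^2))
    br <- prev[which.min(d)]
    rows$bond_ref[k] <- br
    rows$bond[k] <- d[which.min(d)]
    if (k == 2L) next
    cand <- setdiff(prev, br)
    cand <- cand[order(sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[br, ])^2)))]
    ar <- NA_integer_
    for (cc in cand)
      if (ok_angle(xyz[k, ], xyz[br, ], xyz[cc, ])) { ar <- cc; break }
    if (is.na(ar))
      stop("degenerate geometry: all previous atoms collinear with the bond reference")
    rows$angle_ref[k] <- ar
    rows$angle[k] <- measure_angle(xyz[k, ], xyz[br, ], xyz[ar, ])
    if (k == 3L) next
    cand <- setdiff(prev, c(br, ar))
    cand <- cand[order(sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[ar, ])^2)))]
    dr <- NA_integer_
    for (cc in cand)
      if (ok_angle(xyz[br, ], xyz[ar, ], xyz[cc, ])) { dr <- cc; break }
    if (is.na(dr))
      stop("degenerate geometry: no valid dihedral reference")
    rows$dihedral_ref[k] <- dr
    rows$dihedral[k] <- measure_dihedral(xyz[k, ], xyz[br, ], xyz[ar, ], xyz[dr, ])
  }
  zmatrix(rows)
}

# ---------------------------------------------------------------------------
# Plain-text Z-matrix format: one row per line,
#   element [bond_ref bond [angle_ref angle [dihedral_ref dihedral]]]

#' Read Z-matrix text
#' @param text Character scalar or file path.
#' @return A [zmatrix()].
#' @export
read_zmatrix <- function(text) {
  lines <- trimws(read_text_input(text))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty Z-matrix input")
  parse_row <- function(ln, k) {
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    want <- c(1L, 3L, 5L, 7L)[min(k, 4L)]
    if (length(f) != want)
      stop(sprintf("Z-matrix parse error at line %d: expected %d fields", k, want))
    num <- suppressWarnings(as.numeric(f[-1L]))
    if (length(num) && any(is.na(num)))
      stop(sprintf("Z-matrix parse error at line %d: non-numeric field", k))
    list(element = f[1L],
         bond_ref = if (k >= 2L) as.integer(num[1L]) else NA_integer_,
         bond = if (k >= 2L) num[2L] else NA_real_,
         angle_ref = if (k >= 3L) as.integer(num[3L]) else NA_integer_,
         angle = if (k >= 3L) num[4L] else NA_real_,
         dihedral_ref = if (k >= 4L) as.integer(num[5L]) else NA_integer_,
         dihedral = if (k >= 4L) num[6L] else NA_real_)
  }
  rows <- lapply(seq_along(lines), function(k) parse_row(lines[[k]], k))
  zmatrix(data.frame(
    element = vapply(rows, `[[`, "", "element"),
    bond_ref = vapply(rows, `[[`, 1L, "bond_ref"),
    angle_ref = vapply(rows, `[[`, 1L, "angle_ref"),
    dihedral_ref = vapply(rows, `[[`, 1L, "dihedral_ref"),
    bond = vapply(rows, `[[`, 1, "bond"),
    angle = vapply(rows, `[[`, 1, "angle"),
    dihedral = vapply(rows, `[[`, 1, "dihedral"),
    stringsAsFactors = FALSE))
}

#' Write Z-matrix text
#' @param z A [zmatrix()].
#' @return Character scalar.
#' @export
write_zmatrix <- function(z) {
  rows <- z$rows
  out <- vapply(seq_len(nrow(rows)), function(k) {
    if (k == 1L) return(sprintf("%-2s", rows$element[k]))
    if (k == 2L) return(sprintf("%-2s %d %.6f", rows$element[k],
                                rows$bond_ref[k], rows$bond[k]))
    if (k == 3L) return(sprintf("%-2s %d %.6f %d %.6f", rows$element[k],
                                rows$bond_ref[k], rows$bond[k],
                                rows$angle_ref[k], rows$angle[k]))
    sprintf("%-2s %d %.6f %d %.6f %d %.6f", rows$element[k],
            rows$bond_ref[k], rows$bond[k], rows$angle_ref[k], rows$angle[k],
            rows$dihedral_ref[k], rows$dihedral[k])
  }, character(1L))
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# Torsion editing.

# Connected component of `start` in the bond graph with the j-k bond removed.
component_without_bond <- function(bonds, n, j, k, start) {
  adj <- vector("list", n)
  if (nrow(bonds))
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1L]; b <- bonds[r, 2L]
      if ((a == j && b == k) || (a == k && b == j)) next
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Set a torsion angle
#'
#' Rotates the smaller of the two components separated by the central bond
#' so that the dihedral over the given atom quad equals `value`.
#'
#' @param sys A `molsys` object.
#' @param quad Integer vector of 4 atom indices (i, j, k, l); the rotation
#'   axis is the j-k bond.
#' @param value Target dihedral in degrees.
#' @return The modified system.
#' @export
set_torsion <- function(sys, quad, value) {
  stopifnot(length(quad) == 4L)
  i <- quad[1L]; j <- quad[2L]; k <- quad[3L]; l <- quad[4L]
  n <- nrow(sys$atoms)
  side_k <- component_without_bond(sys$bonds, n, j, k, k)
  if (j %in% side_k)
    stop("ring torsion: the central bond lies in a ring")
  side_j <- setdiff(seq_len(n), side_k)
  xyz <- coords(sys)
  cur <- measure_dihedral(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ])
  delta <- wrap_angle(value - cur)
  if (abs(delta) < 1e-12) return(sys)
  move_k_side <- length(side_k) <= length(side_j)
  axis <- vunit(xyz[k, ] - xyz[j, ])
  # a right-handed rotation of the l-side about j->k decreases the
  # measured dihedral, hence the sign flips
  if (move_k_side) {
    moving <- setdiff(side_k, k)
    pivot <- xyz[k, ]
    R <- rotation_matrix(axis, -delta * DEG2RAD)
  } else {
    moving <- setdiff(side_j, j)
    pivot <- xyz[j, ]
    R <- rotation_matrix(axis, delta * DEG2RAD)
  }
  if (length(moving)) {
    rel <- sweep(xyz[moving, , drop = FALSE], 2L, pivot)
    xyz[moving, ] <- sweep(rel %*% t(R), 2L, pivot, "+")
  }
  coords(sys) <- xyz
  sys
}

# ---------------------------------------------------------------------------
# Backbone torsions and Ramachandran classification.

find_atom_in_residue <- function(sys, res_i, name) {
  ix <- residue_atoms(sys, res_i)
  hit <- ix[sys$atoms$name[ix] == name]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Backbone and chi1 torsions of every amino residue
#'
#' phi = C(-1)-N-CA-C, psi = N-CA-C-N(+1), omega = CA(-1)-C(-1)-N-CA,
#' chi1 = N-CA-CB-XG.  Values absent (NA) at chain termini or where atoms
#' are missing.
#'
#' @param sys A `molsys` object.
#' @return `data.frame` with columns `residue`, `name`, `phi`, `psi`,
#'   `omega`, `chi1` (degrees).
#' @export
backbone_torsions <- function(sys) {
  res <- sys$residues
  nres <- nrow(res)
  out <- data.frame(residue = seq_len(nres), name = res$name,
                    phi = NA_real_, psi = NA_real_, omega = NA_real_,
                    chi1 = NA_real_, stringsAsFactors = FALSE)
  xyz <- coords(sys)
  dih <- function(a, b, c, d) {
    if (anyNA(c(a, b, c, d))) return(NA_real_)
    measure_dihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  }
  for (i in seq_len(nres)) {
    if (res$kind[i] != "amino") next
    N <- find_atom_in_residue(sys, i, "N")
    CA <- find_atom_in_residue(sys, i, "CA")
    C <- find_atom_in_residue(sys, i, "C")
    prev_ok <- i > 1L && res$kind[i - 1L] == "amino" &&
      res$chain[i - 1L] == res$chain[i]
    next_ok <- i < nres && res$kind[i + 1L] == "amino" &&
      res$chain[i + 1L] == res$chain[i]
    Cm <- if (prev_ok) find_atom_in_residue(sys, i - 1L, "C") else NA_integer_
    CAm <- if (prev_ok) find_atom_in_residue(sys, i - 1L, "CA") else NA_integer_
    Np <- if (next_ok) find_atom_in_residue(sys, i + 1L, "N") else NA_integer_
    out$phi[i] <- dih(Cm, N, CA, C)
    out$psi[i] <- dih(N, CA, C, Np)
    out$omega[i] <- dih(CAm, Cm, N, CA)
    CB <- find_atom_in_residue(sys, i, "CB")
    XG <- NA_integer_
    if (!is.na(CB)) {
      ix <- residue_atoms(sys, i)
      g <- ix[grepl("^[A-Z]G1?$", sys$atoms$name[ix])]
      if (length(g)) XG <- g[1L]
    }
    out$chi1[i] <- dih(N, CA, CB, XG)
  }
  out
}

# Coarse general-case region polygons in (phi, psi) space.  Favoured: the
# alpha-helical and beta/extended basins; allowed: dilated versions plus the
# left-handed helix basin.  These are deliberately simple convex-ish
# polygons, not the published high-resolution contours.
.rama_regions <- list(
  favoured = list(
    alpha = cbind(c(-140, -140, -40, -40), c(-70, 10, 10, -70)),
    beta  = cbind(c(-170, -170, -50, -50), c(90, 180, 180, 90)),
    beta_low = cbind(c(-170, -170, -50, -50), c(-180, -165, -165, -180))
  ),
  allowed = list(
    alpha = cbind(c(-170, -170, -20, -20), c(-100, 40, 40, -100)),
    beta  = cbind(c(-180, -180, -35, -35), c(60, 180, 180, 60)),
    beta_low = cbind(c(-180, -180, -35, -35), c(-180, -150, -150, -180)),
    lalpha = cbind(c(30, 30, 100, 100), c(-20, 90, 90, -20))
  )
)

#' Classify a backbone conformation on the Ramachandran map
#'
#' Point-in-polygon lookup against coarse general-case favoured/allowed
#' region polygons.
#'
#' @param phi,psi Backbone torsions in degrees.
#' @return One of `"favoured"`, `"allowed"`, `"outlier"`.
#' @export
classify_ramachandran <- function(phi, psi) {
  stopifnot(is.finite(phi), is.finite(psi))
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  for (p in .rama_regions$favoured)
    if (point_in_polygon(phi, psi, p)) return("favoured")
  for (p in .rama_regions$allowed)
    if (point_in_polygon(phi, psi, p)) return("allowed")
  "outlier"
}
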