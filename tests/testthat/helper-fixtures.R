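# Shared builders and oracles for the test suite.  Everything is generated
# in code; fixed seeds make each helper deterministic.

water_pdb_text <- paste(
  "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
  "ATOM      2  H1  HOH A   1       0.957   0.000   0.000  1.00  0.00           H",
  "ATOM      3  H2  HOH A   1      -0.240   0.927   0.000  1.00  0.00           H",
  sep = "\n")

# Minimal system from explicit coordinates.
simple_system <- function(el, xyz, bonds = NULL, charge = 0) {
  xyz <- matrix(xyz, ncol = 3L)
  atoms <- data.frame(serial = seq_along(el), name = el, element = el,
                      ff_type = el, charge = charge,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      residue_index = 1L, stringsAsFactors = FALSE)
  molecular_system(atoms, bonds = bonds)
}

# Chemically sane random chain built through the Z-matrix machinery.
random_chain_system <- function(n, seed, elements = c("C", "N", "O")) {
  set.seed(seed)
  el <- sample(elements, n, replace = TRUE)
  rows <- data.frame(element = el, bond_ref = NA_integer_,
                     angle_ref = NA_integer_, dihedral_ref = NA_integer_,
                     bond = NA_real_, angle = NA_real_, dihedral = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(n)[-1L]) {
    rows$bond_ref[k] <- k - 1L
    rows$bond[k] <- stats::runif(1L, 1.3, 1.5)
  }
  for (k in seq_len(n)[-(1:2)]) {
    rows$angle_ref[k] <- k - 2L
    rows$angle[k] <- stats::runif(1L, 95, 135)
  }
  for (k in seq_len(n)[-(1:3)]) {
    rows$dihedral_ref[k] <- k - 3L
    rows$dihedral[k] <- stats::runif(1L, -180, 180)
  }
  xyz <- zmatrix_to_cartesian(zmatrix(rows))
  sys <- simple_system(el, xyz, bonds = cbind(seq_len(n - 1L), 2:n))
  sys$atoms$charge <- stats::runif(n, -0.3, 0.3)
  sys$atoms$charge <- sys$atoms$charge - mean(sys$atoms$charge)
  sys
}

# Central-difference gradient oracle.
fd_gradient <- function(sys, topo, params, settings, h = 1e-5) {
  n <- nrow(sys$atoms)
  num <- matrix(0, n, 3L)
  for (i in seq_len(n))
    for (c in 1:3) {
      sp <- sys
      xm <- coords(sp)
      xm[i, c] <- xm[i, c] + h
      coords(sp) <- xm
      ep <- energy_and_gradient(sp, topo, params, settings)$energy$total
      xm[i, c] <- xm[i, c] - 2 * h
      coords(sp) <- xm
      em <- energy_and_gradient(sp, topo, params, settings)$energy$total
      num[i, c] <- (ep - em) / (2 * h)
    }
  num
}

# Valid random Z-matrix (angles well away from collinearity).
random_zmatrix <- function(n, seed) {
  set.seed(seed)
  rows <- data.frame(element = "C", bond_ref = NA_integer_,
                     angle_ref = NA_integer_, dihedral_ref = NA_integer_,
                     bond = NA_real_, angle = NA_real_, dihedral = NA_real_,
                     stringsAsFactors = FALSE)
  rows <- rows[rep(1L, n), ]
  rownames(rows) <- NULL
  pick <- function(pool) pool[sample.int(length(pool), 1L)]
  for (k in seq_len(n)[-1L]) {
    rows$bond_ref[k] <- pick(seq_len(k - 1L))
    rows$bond[k] <- stats::runif(1L, 1.0, 1.8)
  }
  for (k in seq_len(n)[-(1:2)]) {
    rows$angle_ref[k] <- pick(setdiff(seq_len(k - 1L), rows$bond_ref[k]))
    rows$angle[k] <- stats::runif(1L, 15, 165)
  }
  for (k in seq_len(n)[-(1:3)]) {
    rows$dihedral_ref[k] <- pick(setdiff(seq_len(k - 1L),
                                         c(rows$bond_ref[k],
                                           rows$angle_ref[k])))
    rows$dihedral[k] <- stats::runif(1L, -179, 179)
  }
  zmatrix(rows)
}

expect_rigid_equal <- function(a, b, tol = 1e-8) {
  expect_lt(kabsch(a, b)$rmsd, tol)
}
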