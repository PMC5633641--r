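# Deterministic generators for test inputs: a self-contained generic
# parameter set, polyalanine peptides, a rigid-cage docking pocket, toy
# crystals, a Lennard-Jones fluid and synthetic distance histograms.
# All fixtures are code: the same arguments always produce bitwise-identical
# objects, and each generator checks its own invariants before returning.

#' Generic toy force-field parameter set
#'
#' Complete bonded and nonbonded parameters for systems typed by element
#' over {H, C, N, O, S}: harmonic bonds with r0 = covalent-radius sums,
#' generic angles, one 3-fold wildcard torsion per central pair, and
#' element LJ parameters.  Physically plausible magnitudes; not fitted to
#' any published force field.
#'
#' @return A [parameter_set()].
#' @export
make_toy_paramset <- function() {
  els <- c("H", "C", "N", "O", "S")
  p <- parameter_set()
  for (i in seq_along(els))
    for (j in seq_len(i)) {
      e1 <- els[i]; e2 <- els[j]
      r0 <- element_covalent_radius(e1) + element_covalent_radius(e2)
      k <- if ("H" %in% c(e1, e2)) 340 else 300
      p$bond[[param_key(c(e1, e2))]] <- c(k, r0)
      p$torsion[[param_key(c("X", e2, e1, "X"))]] <- list(c(0.5, 3, 0))
    }
  for (i in seq_along(els))
    for (j in seq_along(els))
      for (k in seq_along(els))
        if (j >= 1L) {
          key <- param_key(c(els[i], els[j], els[k]))
          if (is.null(lookup_or_rev(p$angle, c(els[i], els[j], els[k]))))
            p$angle[[key]] <- c(50, 109.5)
        }
  p$lj <- list(H = c(2.50, 0.016), C = c(3.40, 0.086), N = c(3.25, 0.170),
               O = c(3.00, 0.210), S = c(3.56, 0.250))
  stopifnot(all(vapply(p$bond, function(b)
    b[2L] >= 0.6 && b[2L] <= 2.2, TRUE)))
  p
}

# Append one backbone atom by NeRF placement; wraps place_atom with
# degrees interface.  refs = indices (bond, angle, dihedral).
.place <- function(xyz, refs, r, ang, dih) {
  rbind(xyz, place_atom(xyz[refs[3L], ], xyz[refs[2L], ], xyz[refs[1L], ],
                        r, ang, dih))
}

#' Build a polyalanine peptide
#'
#' Backbone built residue-by-residue from ideal internal coordinates at
#' the requested (phi, psi): helix (-60, -45) or extended (-180, 180);
#' side chains and hydrogens from the residue templates.  Charges are
#' assigned by [assign_simple_charges()] with neutral per-residue groups.
#'
#' @param n_residues Number of residues (>= 1).
#' @param conformation `"helix"` or `"extended"`.
#' @return A `molsys` of n alanine residues.
#' @export
make_polyala <- function(n_residues, conformation = c("helix", "extended")) {
  conformation <- match.arg(conformation)
  if (n_residues < 1L) stop("need at least one residue")
  tors <- if (conformation == "helix") c(phi = -60, psi = -45)
          else c(phi = -180, psi = 180)
  omega <- 180
  # heavy backbone: N, CA, C per residue (O added after)
  xyz <- matrix(c(0, 0, 0), 1L)                 # N1
  xyz <- rbind(xyz, c(1.46, 0, 0))              # CA1
  th <- 110.5 * DEG2RAD
  xyz <- rbind(xyz, xyz[2L, ] +
                 1.52 * c(cos(pi - th), sin(pi - th), 0))  # C1 (angle N-CA-C)
  for (i in seq_len(n_residues - 1L)) {
    b <- 3L * i
    # N(i+1): psi(i) about CA(i)-C(i)
    xyz <- .place(xyz, c(b, b - 1L, b - 2L), 1.33, 116.6, tors["psi"])
    # CA(i+1): omega about C(i)-N(i+1)
    xyz <- .place(xyz, c(b + 1L, b, b - 1L), 1.46, 121.9, omega)
    # C(i+1): phi about N(i+1)-CA(i+1)
    xyz <- .place(xyz, c(b + 2L, b + 1L, b), 1.52, 110.5, tors["phi"])
  }
  # carbonyl oxygens: anti to the next N (or to psi for the C-terminus)
  atoms <- list(); bonds <- list(); oxy <- list()
  for (i in seq_len(n_residues)) {
    b <- 3L * (i - 1L)
    oxy[[i]] <- place_atom(xyz[b + 1L, ], xyz[b + 2L, ], xyz[b + 3L, ],
                           1.23, 120.5, wrap_angle(tors["psi"] + 180))
  }
  n_bb <- 3L * n_residues
  names_bb <- rep(c("N", "CA", "C"), n_residues)
  el_bb <- rep(c("N", "C", "C"), n_residues)
  all_xyz <- rbind(xyz, do.call(rbind, oxy))
  names_all <- c(names_bb, rep("O", n_residues))
  el_all <- c(el_bb, rep("O", n_residues))
  resi <- c(rep(seq_len(n_residues), each = 3L), seq_len(n_residues))
  atoms <- data.frame(serial = seq_along(names_all), name = names_all,
                      element = el_all, ff_type = el_all, charge = 0,
                      x = all_xyz[, 1L], y = all_xyz[, 2L],
                      z = all_xyz[, 3L], residue_index = resi,
                      stringsAsFactors = FALSE)
  residues <- data.frame(name = "ALA", chain = "A",
                         seqnum = seq_len(n_residues), icode = "",
                         kind = "amino", variant = "",
                         stringsAsFactors = FALSE)
  bonds <- do.call(rbind, c(
    lapply(seq_len(n_residues), function(i) {
      b <- 3L * (i - 1L)
      rbind(c(b + 1L, b + 2L), c(b + 2L, b + 3L),      # N-CA, CA-C
            c(b + 3L, n_bb + i))                        # C-O
    }),
    lapply(seq_len(n_residues - 1L), function(i)
      matrix(c(3L * i, 3L * i + 1L), 1L))))             # C(i)-N(i+1)
  # order atoms by residue so residue_atoms is contiguous-ish (not required)
  sys <- molecular_system(atoms, residues, bonds)
  for (i in seq_len(n_residues)) {
    sys <- build_sidechain(sys, i, "ALA")
    sys <- add_residue_hydrogens(sys, i)
  }
  sys <- assign_simple_charges(sys)
  stopifnot(nrow(sys$residues) == n_residues,
            all(abs(vapply(sys$charge_groups, function(g)
              sum(sys$atoms$charge[g]), 0)) < 1e-9))
  sys
}

#' Rigid-cage docking pocket with a flexible ligand
#'
#' A spherical cage of carbon atoms (radius tuned so the cage interior is
#' attractive at the centre) plus a small three-atom flexible ligand
#' placed off-centre.  Selections are attached as attributes
#' `receptor_atoms` and `ligand_atoms`.
#'
#' @param seed Integer seed (controls the small random ligand offset).
#' @return A `molsys` with residues `CAG` (rigid receptor) and `LIG`.
#' @export
make_toy_pocket <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cage <- sphere_points(14L) * 4.6
  lig0 <- rbind(c(-1.4, 0, 0), c(0, 0.4, 0), c(1.4, 0, 0))
  offset <- stats::runif(3L, -0.6, 0.6) + c(0.9, 0, 0)
  lig <- sweep(lig0, 2L, offset, "+")
  n_c <- nrow(cage)
  atoms <- data.frame(
    serial = seq_len(n_c + 3L),
    name = c(sprintf("C%d", seq_len(n_c)), "C1", "C2", "C3"),
    element = "C", ff_type = "C", charge = 0,
    x = c(cage[, 1L], lig[, 1L]), y = c(cage[, 2L], lig[, 2L]),
    z = c(cage[, 3L], lig[, 3L]),
    residue_index = c(rep(1L, n_c), rep(2L, 3L)),
    stringsAsFactors = FALSE)
  residues <- data.frame(name = c("CAG", "LIG"), chain = c("A", "A"),
                         seqnum = 1:2, icode = "", kind = c("other", "ligand"),
                         variant = "", stringsAsFactors = FALSE)
  bonds <- rbind(c(n_c + 1L, n_c + 2L), c(n_c + 2L, n_c + 3L))
  sys <- molecular_system(atoms, residues, bonds)
  attr(sys, "receptor_atoms") <- seq_len(n_c)
  attr(sys, "ligand_atoms") <- n_c + 1:3
  sys
}

#' Toy crystals with a known-by-scan optimal lattice constant
#'
#' `lj_cubic`: one neutral LJ pseudo-atom per cubic P1 cell; the optimal
#' lattice constant under the truncated supercell sum is found by a 1-D
#' golden-section scan at build time and stored as attribute `a_opt`.
#' `diatomic_ionic`: two opposite charges (one neutral charge group) per
#' cubic cell.
#'
#' @param kind `"lj_cubic"` or `"diatomic_ionic"`.
#' @param params Parameter set used for the build-time scan (default
#'   [make_toy_paramset()]).
#' @param n Supercell dimension used in the scan.
#' @return A [crystal_system()]; for `lj_cubic` the attribute `a_opt`
#'   holds the scan optimum (Angstrom).
#' @export
make_toy_crystal <- function(kind = c("lj_cubic", "diatomic_ionic"),
                             params = make_toy_paramset(), n = 5L) {
  kind <- match.arg(kind)
  if (kind == "lj_cubic") {
    make <- function(a) {
      atoms <- data.frame(serial = 1L, name = "C", element = "C",
                          ff_type = "C", charge = 0, x = 0, y = 0, z = 0,
                          residue_index = 1L, stringsAsFactors = FALSE)
      crystal_system(unit_cell(a, a, a), molecular_system(atoms))
    }
    topo <- perceive_topology(make(4)$contents)
    settings <- nonbonded_settings(cutoff = 9.0)
    ener <- function(a)
      lattice_energy(make(a), topo, params, settings, n)$total
    # golden-section scan around the LJ well
    lo <- 3.0; hi <- 5.5
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- ener(x1); f2 <- ener(x2)
    while (hi - lo > 1e-4) {
      if (f1 < f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- ener(x1)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- ener(x2)
      }
    }
    a_opt <- (lo + hi) / 2
    cr <- make(a_opt)
    stopifnot(ener(a_opt) < 0)
    attr(cr, "a_opt") <- a_opt
    cr
  } else {
    a <- 4.0
    atoms <- data.frame(
      serial = 1:2, name = c("N", "O"), element = c("N", "O"),
      ff_type = c("N", "O"), charge = c(0.5, -0.5),
      x = c(0, a / 2), y = c(0, a / 2), z = c(0, a / 2),
      residue_index = 1L, stringsAsFactors = FALSE)
    sys <- molecular_system(atoms, charge_groups = list(1:2),
                            neutralised = TRUE)
    cr <- crystal_system(unit_cell(a, a, a), sys)
    stopifnot(abs(sum(sys$atoms$charge)) < 1e-12)
    cr
  }
}

#' Periodic Lennard-Jones toy fluid
#'
#' `n` carbon pseudo-atoms on a cubic lattice in an orthorhombic periodic
#' box at reduced density ~0.5 (argon-like LJ well via the fluid parameter
#' set returned alongside).
#'
#' @param n Particle count (a perfect cube; default 64).
#' @param sigma,epsilon LJ parameters (default 3.4 A, 0.238 kcal/mol).
#' @return List: `system` (with `box`), `params`, `settings`.
#' @export
make_lj_fluid <- function(n = 64L, sigma = 3.4, epsilon = 0.238) {
  side <- round(n^(1 / 3))
  if (side^3 != n) stop("n must be a perfect cube")
  L <- (2 * n)^(1 / 3) * sigma          # reduced density 0.5
  sp <- L / side
  g <- as.matrix(expand.grid(0:(side - 1L), 0:(side - 1L), 0:(side - 1L)))
  xyz <- (g + 0.5) * sp
  atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      ff_type = "C", charge = 0,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      residue_index = 1L, stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, box = c(L, L, L))
  params <- parameter_set(lj = list(C = c(sigma, epsilon)))
  settings <- nonbonded_settings(cutoff = min(8.0, L / 2 * 0.99),
                                 dsf_alpha = 0.2)
  list(system = sys, params = params, settings = settings)
}

#' Synthetic distance histograms from a known potential
#'
#' Metropolis sampling of r from exp(-U(r)/kBT) r^2 on \[r_min, r_max\],
#' histogrammed on a uniform grid, plus the matching r^2-weighted uniform
#' reference.  Used to test Boltzmann-inversion recovery.
#'
#' @param potential Function U(r) in kcal/mol, bounded below.
#' @param n_samples Metropolis samples kept (after thinning).
#' @param seed Integer seed.
#' @param T Temperature (K).
#' @param r_min,r_max,bin_width Range and binning (Angstrom).
#' @param thin Keep every `thin`-th Metropolis step (reduces the serial
#'   correlation of the chain so histogram counts are close to
#'   multinomial).
#' @return List: `observed`, `reference` (both [distance_histogram()]).
#' @export
make_synthetic_histograms <- function(potential, n_samples = 20000L,
                                      seed = 1L, T = 300,
                                      r_min = 1, r_max = 8,
                                      bin_width = 0.2, thin = 10L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kT <- KB_KCAL * T
  logw <- function(r) -potential(r) / kT + 2 * log(r)
  r <- (r_min + r_max) / 2
  lw <- logw(r)
  out <- numeric(n_samples)
  kept <- 0L
  step <- 0L
  # proposals are drawn in blocks to keep the chain loop cheap
  nprop <- n_samples * thin
  prop <- stats::runif(nprop, -1.5, 1.5)
  acc <- stats::runif(nprop)
  while (kept < n_samples) {
    step <- step + 1L
    rp <- r + prop[step]
    if (rp > r_min && rp < r_max) {
      lwp <- logw(rp)
      if (log(acc[step]) < lwp - lw) { r <- rp; lw <- lwp }
    }
    if (step %% thin == 0L) {
      kept <- kept + 1L
      out[kept] <- r
    }
  }
  edges <- seq(r_min, r_max, by = bin_width)
  counts <- tabulate(findInterval(out, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centres <- (edges[-1L] + edges[-length(edges)]) / 2
  ref <- centres^2                      # r^2-weighted uniform reference
  list(observed = distance_histogram(c("A", "B"), edges, counts),
       reference = distance_histogram(c("A", "B"), edges,
                                      ref / sum(ref) * sum(counts)))
}
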