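# Unit cells, supercell expansion and lattice-sum energetics.
#
# The crystal environment is approximated by an n x n x n grid of copies of
# the unit cell (default 5) with the reference cell at the centre.
# Electrostatics between cell and image atoms are summed over neutral charge
# groups: a pair of groups is included whole, or not at all, by the distance
# between the group centres (realising neutral-group truncation without
# lattice summation).

#' Construct a unit cell
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @param symmetry_ops List of symmetry operators, each
#'   `list(R = 3x3 fractional rotation, t = fractional translation)`;
#'   the identity is always prepended if absent.
#' @return Object of class `unit_cell` with the Cartesian cell matrix
#'   (a along x, b in the xy plane) precomputed.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      symmetry_ops = list()) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * DEG2RAD); cb <- cos(beta * DEG2RAD)
  cg <- cos(gamma * DEG2RAD); sg <- sin(gamma * DEG2RAD)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 1e-12) stop("degenerate cell: volume is zero")
  # cell matrix columns = lattice vectors, a along x, b in xy
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0, c * sqrt(vfac) / sg), 3L, 3L, byrow = TRUE)
  ident <- list(R = diag(3L), t = c(0, 0, 0))
  has_id <- any(vapply(symmetry_ops, function(op)
    isTRUE(all.equal(op$R, diag(3L))) && all(abs(op$t) < 1e-12), TRUE))
  if (!has_id) symmetry_ops <- c(list(ident), symmetry_ops)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, matrix = M,
                 symmetry_ops = symmetry_ops),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Cell volume
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) abs(det(cell$matrix))

#' Fractional to Cartesian coordinates
#' @param cell A [unit_cell()].
#' @param frac N x 3 matrix of fractional coordinates.
#' @return N x 3 Cartesian matrix (Angstrom).
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- matrix(frac, ncol = 3L)
  t(cell$matrix %*% t(frac))
}

#' Cartesian to fractional coordinates
#' @param cell A [unit_cell()].
#' @param cart N x 3 Cartesian matrix.
#' @return N x 3 fractional matrix.
#' @export
cart_to_frac <- function(cell, cart) {
  cart <- matrix(cart, ncol = 3L)
  t(solve(cell$matrix) %*% t(cart))
}

#' Bundle a unit cell with its molecular contents
#'
#' @param cell A [unit_cell()].
#' @param contents A `molsys` holding the full cell contents in Cartesian
#'   Angstrom (asymmetric unit already expanded).
#' @return Object of class `crystal_system`.
#' @export
crystal_system <- function(cell, contents) {
  stopifnot(inherits(cell, "unit_cell"), inherits(contents, "molsys"))
  structure(list(cell = cell, contents = contents), class = "crystal_system")
}

#' @export
print.crystal_system <- function(x, ...) {
  cat("<crystal_system>\n  ")
  print(x$cell)
  cat("  ")
  print(x$contents)
  invisible(x)
}

#' Apply the cell's symmetry operators to an asymmetric unit
#'
#' @param cell A [unit_cell()].
#' @param asu A `molsys` holding the asymmetric unit.
#' @return A `molsys` with one copy of the asymmetric unit per operator.
#' @export
expand_symmetry <- function(cell, asu) {
  ops <- cell$symmetry_ops
  if (length(ops) == 1L) return(asu)
  out <- asu
  frac <- cart_to_frac(cell, coords(asu))
  for (k in seq_along(ops)[-1L]) {
    f2 <- sweep(frac %*% t(ops[[k]]$R), 2L, ops[[k]]$t, "+")
    copy <- asu
    coords(copy) <- frac_to_cart(cell, f2)
    out <- merge_systems(out, copy)
  }
  out
}

# Concatenate two systems (atoms, residues, bonds, charge groups).
merge_systems <- function(a, b) {
  n0 <- nrow(a$atoms)
  r0 <- nrow(a$residues)
  atoms_b <- b$atoms
  atoms_b$residue_index <- atoms_b$residue_index + r0
  atoms_b$serial <- atoms_b$serial + max(a$atoms$serial)
  atoms <- rbind(a$atoms, atoms_b)
  residues <- rbind(a$residues, b$residues)
  bonds <- rbind(a$bonds, b$bonds + n0)
  cg <- c(a$charge_groups, lapply(b$charge_groups, function(g) g + n0))
  molecular_system(atoms, residues, bonds, cg, a$box, FALSE)
}

#' Integer translations of a supercell grid
#'
#' @param n Odd grid dimension (5 gives the 5 x 5 x 5 grid of 125 cells).
#' @return n^3 x 3 integer matrix of cell translations, centred on (0,0,0).
#' @export
build_supercell <- function(n = 5L) {
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("supercell dimension must be odd")
  h <- (n - 1L) %/% 2L
  g <- expand.grid(i = -h:h, j = -h:h, k = -h:h)
  m <- as.matrix(g[order(abs(g$i) + abs(g$j) + abs(g$k)), , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Nonbonded (LJ + plain-Coulomb) interaction between the cell contents and
# one translated image, summed over whole charge-group pairs selected by
# group-centre distance <= cutoff.  Returns energy and, optionally, the
# gradient contributions on the cell atoms (both roles: as cell atom and as
# the generator of its image copy).
image_interaction <- function(atoms_xyz, q, sig, eps, groups, gcent, tvec,
                              settings, grad = FALSE) {
  ng <- length(groups)
  img_cent <- sweep(gcent, 2L, tvec, "+")
  e <- 0
  g <- if (grad) matrix(0, nrow(atoms_xyz), 3L) else NULL
  for (ga in seq_len(ng)) {
    for (gb in seq_len(ng)) {
      dc <- gcent[ga, ] - img_cent[gb, ]
      if (sqrt(sum(dc * dc)) > settings$cutoff) next
      ia <- groups[[ga]]; ib <- groups[[gb]]
      pa <- atoms_xyz[ia, , drop = FALSE]
      pb <- sweep(atoms_xyz[ib, , drop = FALSE], 2L, tvec, "+")
      for (u in seq_along(ia)) {
        d <- sweep(pb, 2L, pa[u, ], "-")
        r <- sqrt(rowSums(d * d))
        s <- (sig[ia[u]] + sig[ib]) / 2
        ee <- sqrt(eps[ia[u]] * eps[ib])
        sr6 <- (s / r)^6
        elj <- 4 * ee * (sr6^2 - sr6)
        ecl <- settings$coulomb_const * q[ia[u]] * q[ib] / r
        e <- e + sum(elj + ecl)
        if (grad) {
          dedr <- 4 * ee * (-12 * sr6^2 + 6 * sr6) / r -
            settings$coulomb_const * q[ia[u]] * q[ib] / r^2
          gv <- d * (dedr / r)          # dE/d(pb), and -gv on pa
          g[ia[u], ] <- g[ia[u], ] - colSums(gv)
          g[ib, ] <- g[ib, ] + gv
        }
      }
    }
  }
  list(e = e, g = g)
}

#' Lattice energy of a crystal on a supercell grid
#'
#' `intra_cell` is the full force-field energy of the cell contents;
#' `inter_image` is half the sum over all non-central images of the
#' cell-image nonbonded energy (LJ + group-truncated plain Coulomb).
#'
#' @param crystal A [crystal_system()] whose contents carry charges in
#'   neutral groups.
#' @param topo,params,settings Force-field inputs for the cell contents.
#' @param n Supercell dimension (odd; default 5).
#' @param force Set TRUE to proceed with non-neutral charge groups.
#' @return List of class `lattice_energy`: `intra_cell`, `inter_image`,
#'   `total` (kcal/mol per unit cell).
#' @export
lattice_energy <- function(crystal, topo, params,
                           settings = nonbonded_settings(), n = 5L,
                           force = FALSE) {
  sys <- crystal$contents
  gsum <- vapply(sys$charge_groups, function(ix) sum(sys$atoms$charge[ix]), 0)
  if (any(abs(gsum) > 1e-6) && !force) {
    warning("charge groups are not neutral; refusing electrostatic lattice sum (use force = TRUE)")
    stop("non-neutral charge groups")
  }
  intra <- energy_and_gradient(sys, topo, params, settings)$energy$total
  xyz <- coords(sys)
  q <- sys$atoms$charge
  types <- sys$atoms$ff_type
  ljp <- vapply(types, function(t) lookup_lj_param(params, t), numeric(2L))
  sig <- ljp[1L, ]; eps <- ljp[2L, ]
  groups <- sys$charge_groups
  gcent <- t(vapply(groups, function(ix)
    colMeans(xyz[ix, , drop = FALSE]), numeric(3L)))
  trans <- build_supercell(n)
  inter <- 0
  for (r in seq_len(nrow(trans))) {
    tv <- trans[r, ]
    if (all(tv == 0L)) next
    tvec <- as.vector(crystal$cell$matrix %*% tv)
    inter <- inter + image_interaction(xyz, q, sig, eps, groups, gcent,
                                       tvec, settings)$e
  }
  inter <- inter / 2
  structure(list(intra_cell = intra, inter_image = inter,
                 total = intra + inter),
            class = "lattice_energy")
}

#' @export
print.lattice_energy <- function(x, ...) {
  cat(sprintf("<lattice_energy> intra %.6f + inter %.6f = %.6f kcal/mol/cell\n",
              x$intra_cell, x$inter_image, x$total))
  invisible(x)
}

# Gradient of the lattice energy w.r.t. the Cartesian coordinates of the
# cell atoms (analytic: intra-cell force-field gradient plus both-role
# image contributions, halved like the energy).
lattice_gradient <- function(crystal, topo, params, settings, n = 5L) {
  sys <- crystal$contents
  eg <- energy_and_gradient(sys, topo, params, settings)
  xyz <- coords(sys)
  q <- sys$atoms$charge
  types <- sys$atoms$ff_type
  ljp <- vapply(types, function(t) lookup_lj_param(params, t), numeric(2L))
  sig <- ljp[1L, ]; eps <- ljp[2L, ]
  groups <- sys$charge_groups
  gcent <- t(vapply(groups, function(ix)
    colMeans(xyz[ix, , drop = FALSE]), numeric(3L)))
  trans <- build_supercell(n)
  g <- matrix(0, nrow(xyz), 3L)
  e <- 0
  for (r in seq_len(nrow(trans))) {
    tv <- trans[r, ]
    if (all(tv == 0L)) next
    tvec <- as.vector(crystal$cell$matrix %*% tv)
    ii <- image_interaction(xyz, q, sig, eps, groups, gcent, tvec,
                            settings, grad = TRUE)
    e <- e + ii$e
    g <- g + ii$g
  }
  list(energy = eg$energy$total + e / 2, gradient = eg$gradient + g / 2)
}

#' Optimise crystal geometry and (optionally) cell parameters
#'
#' Joint minimisation over atomic Cartesians and, when `optimise_cell`,
#' the six cell parameters (gradients over cell parameters by central
#' finite differences; contents are held in Cartesian coordinates while
#' the cell varies).  Uses the Powell-Beale conjugate-gradient minimiser.
#'
#' @param crystal A [crystal_system()].
#' @param topo,params,settings Force-field inputs.
#' @param optimise_cell Logical: relax a, b, c, alpha, beta, gamma too.
#' @param n Supercell dimension.
#' @param grad_tol,max_iter Convergence controls (see
#'   [minimizer_options()]).
#' @return List: `crystal` (optimised), `result` (optimiser summary).
#' @export
optimize_crystal <- function(crystal, topo, params,
                             settings = nonbonded_settings(),
                             optimise_cell = FALSE, n = 5L,
                             grad_tol = 0.1, max_iter = 500L) {
  sys0 <- crystal$contents
  natom <- nrow(sys0$atoms)
  cell0 <- crystal$cell
  v0 <- cell_volume(cell0)
  cellvec0 <- c(cell0$a, cell0$b, cell0$c, cell0$alpha, cell0$beta,
                cell0$gamma)
  make_crystal <- function(x) {
    xyz <- matrix(x[seq_len(3L * natom)], ncol = 3L, byrow = TRUE)
    cl <- if (optimise_cell) {
      cp <- x[3L * natom + 1:6]
      unit_cell(cp[1L], cp[2L], cp[3L], cp[4L], cp[5L], cp[6L],
                cell0$symmetry_ops[-1L])
    } else cell0
    s <- sys0
    coords(s) <- xyz
    crystal_system(cl, s)
  }
  fn <- function(x) {
    cr <- tryCatch(make_crystal(x), error = function(e) NULL)
    if (is.null(cr)) return(Inf)
    if (cell_volume(cr$cell) < 0.2 * v0)
      stop("cell collapse: volume fell below 20% of the starting volume")
    lattice_gradient(cr, topo, params, settings, n)$energy
  }
  gr <- function(x) {
    cr <- make_crystal(x)
    lg <- lattice_gradient(cr, topo, params, settings, n)
    g <- as.vector(t(lg$gradient))
    if (optimise_cell) {
      cp <- x[3L * natom + 1:6]
      gcell <- vapply(1:6, function(k) {
        h <- max(1e-4 * abs(cp[k]), 1e-5)
        xp <- x; xp[3L * natom + k] <- cp[k] + h
        xm <- x; xm[3L * natom + k] <- cp[k] - h
        (fn(xp) - fn(xm)) / (2 * h)
      }, 0)
      g <- c(g, gcell)
    }
    g
  }
  x0 <- as.vector(t(coords(sys0)))
  if (optimise_cell) x0 <- c(x0, cellvec0)
  res <- opt_cg_powell_beale(fn, gr, x0, grad_tol = grad_tol,
                             max_iter = max_iter)
  out <- make_crystal(res$x)
  list(crystal = out,
       result = structure(list(system = out$contents, energy = res$f,
                               avg_grad = avg_atom_gradient(res$g),
                               iterations = res$iterations,
                               converged = res$converged,
                               trace = res$trace, message = res$message,
                               method = "cg_powell_beale"),
                          class = "min_result"))
}
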