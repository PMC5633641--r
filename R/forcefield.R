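# AMBER/GAFF-functional-form energy and analytic gradient.
#
#   E = sum k_b (r - r0)^2  +  sum k_a (theta - theta0)^2
#     + sum (Vn/2)(1 + cos(n phi - gamma))
#     + LJ 12-6 (Lorentz-Berthelot combining)  +  DSF electrostatics
#
# Units: kcal/mol, Angstrom, elementary charges; radians inside the kernels,
# degrees at file interfaces.  1-2 and 1-3 pairs are excluded, 1-4 pairs
# scaled.  Electrostatics use the damped-shifted-force (DSF) form: erfc
# damping plus energy and force shifts so both vanish at the cutoff, which
# makes plain cutoff truncation well-behaved without lattice summation.

#' Nonbonded interaction settings
#'
#' @param cutoff Pair cutoff Rc in Angstrom.
#' @param dsf_alpha DSF damping parameter in 1/Angstrom.
#' @param scale14_lj,scale14_coul Scale factors applied to 1-4 pairs
#'   (AMBER convention: 1/2 and 1/1.2).
#' @param coulomb_const Coulomb constant in kcal A / (mol e^2).
#' @return List of class `nb_settings`.
#' @export
nonbonded_settings <- function(cutoff = 9.0, dsf_alpha = 0.2,
                               scale14_lj = 1 / 2.0,
                               scale14_coul = 1 / 1.2,
                               coulomb_const = 332.0636) {
  stopifnot(cutoff > 0, dsf_alpha >= 0)
  structure(list(cutoff = cutoff, dsf_alpha = dsf_alpha,
                 scale14_lj = scale14_lj, scale14_coul = scale14_coul,
                 coulomb_const = coulomb_const),
            class = "nb_settings")
}

#' Damped-shifted-force pair electrostatic energy
#'
#' For r <= Rc:
#' `E = C q1 q2 (erfc(a r)/r - erfc(a Rc)/Rc
#'      + (erfc(a Rc)/Rc^2 + 2a/sqrt(pi) exp(-a^2 Rc^2)/Rc) (r - Rc))`
#' and 0 beyond the cutoff; both E and dE/dr vanish continuously at Rc.
#'
#' @param q1,q2 Charges in e.
#' @param r Distance(s) in Angstrom.
#' @param settings A [nonbonded_settings()].
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
dsf_pair_energy <- function(q1, q2, r, settings = nonbonded_settings()) {
  if (any(r <= 0)) stop("singularity: r must be positive")
  a <- settings$dsf_alpha
  Rc <- settings$cutoff
  C <- settings$coulomb_const
  shift_e <- erfc(a * Rc) / Rc
  shift_f <- erfc(a * Rc) / Rc^2 + 2 * a / sqrt(pi) * exp(-a^2 * Rc^2) / Rc
  e <- C * q1 * q2 * (erfc(a * r) / r - shift_e + shift_f * (r - Rc))
  e[r > Rc] <- 0
  e
}

# dE/dr of the DSF pair term (vectorised), zero beyond cutoff.
dsf_pair_dedr <- function(q1, q2, r, settings) {
  a <- settings$dsf_alpha
  Rc <- settings$cutoff
  C <- settings$coulomb_const
  shift_f <- erfc(a * Rc) / Rc^2 + 2 * a / sqrt(pi) * exp(-a^2 * Rc^2) / Rc
  g <- C * q1 * q2 * (-erfc(a * r) / r^2 -
                        2 * a / sqrt(pi) * exp(-a^2 * r^2) / r + shift_f)
  g[r > Rc] <- 0
  g
}

# ---------------------------------------------------------------------------
# Parameter sets.

#' Construct a force-field parameter set
#'
#' @param bond Named list `"T1-T2" -> c(k, r0)` (kcal/mol/A^2, A).
#' @param angle Named list `"T1-T2-T3" -> c(k, theta0_deg)`.
#' @param torsion Named list `"T1-T2-T3-T4" -> list(c(V2, n, gamma_deg), ...)`;
#'   `X` matches any type.
#' @param lj Named list `"T" -> c(sigma, epsilon)`.
#' @param charge Optional named list `"T" -> q` of per-type default charges.
#' @param improper Optional named list like `torsion` for improper quads.
#' @return Object of class `paramset`.
#' @export
parameter_set <- function(bond = list(), angle = list(), torsion = list(),
                          lj = list(), charge = list(), improper = list()) {
  structure(list(bond = bond, angle = angle, torsion = torsion, lj = lj,
                 charge = charge, improper = improper),
            class = "paramset")
}

param_key <- function(types) paste(types, collapse = "-")

lookup_or_rev <- function(tbl, types) {
  v <- tbl[[param_key(types)]]
  if (is.null(v)) v <- tbl[[param_key(rev(types))]]
  v
}

lookup_bond_param <- function(params, types) {
  v <- lookup_or_rev(params$bond, types)
  if (is.null(v)) stop("missing bond parameter for (",
                       param_key(types), ")")
  v
}

lookup_angle_param <- function(params, types) {
  v <- lookup_or_rev(params$angle, types)
  if (is.null(v)) stop("missing angle parameter for (",
                       param_key(types), ")")
  v
}

lookup_torsion_param <- function(tbl, types) {
  v <- lookup_or_rev(tbl, types)
  if (!is.null(v)) return(v)
  wc <- c("X", types[2:3], "X")
  v <- lookup_or_rev(tbl, wc)
  v
}

lookup_lj_param <- function(params, type) {
  v <- params$lj[[type]]
  if (is.null(v)) stop("missing LJ parameter for type (", type, ")")
  v
}

#' @export
print.paramset <- function(x, ...) {
  cat(sprintf("<paramset> %d bond, %d angle, %d torsion, %d LJ types\n",
              length(x$bond), length(x$angle), length(x$torsion),
              length(x$lj)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter file dialect: versioned header, whitespace-separated records.
#   mmforge-params 1
#   bond    C C   310.0 1.526
#   angle   C C C  40.0 109.5
#   torsion C C C C  1.4 3 0.0     (V/2, periodicity, phase deg; accumulate)
#   lj      C 3.40 0.086
#   charge  C -0.10

#' Read a parameter file
#' @param text Character scalar or file path.
#' @return A [parameter_set()].
#' @export
read_params <- function(text) {
  lines <- trimws(read_text_input(text))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || !grepl("^mmforge-params\\s+1$", lines[[1L]]))
    stop("parameter file must start with header 'mmforge-params 1'")
  p <- parameter_set()
  for (ln in lines[-1L]) {
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    kind <- f[1L]
    if (kind == "bond") {
      p$bond[[param_key(f[2:3])]] <- as.numeric(f[4:5])
    } else if (kind == "angle") {
      p$angle[[param_key(f[2:4])]] <- as.numeric(f[5:6])
    } else if (kind %in% c("torsion", "improper")) {
      key <- param_key(f[2:5])
      term <- as.numeric(f[6:8])
      p[[kind]][[key]] <- c(p[[kind]][[key]], list(term))
    } else if (kind == "lj") {
      p$lj[[f[2L]]] <- as.numeric(f[3:4])
    } else if (kind == "charge") {
      p$charge[[f[2L]]] <- as.numeric(f[3L])
    } else stop("unknown parameter record '", kind, "'")
  }
  p
}

#' Write a parameter file
#' @param params A [parameter_set()].
#' @return Character scalar in the package's parameter dialect.
#' @export
write_params <- function(params) {
  out <- "mmforge-params 1"
  for (k in names(params$bond))
    out <- c(out, sprintf("bond %s %.6g %.6g",
                          gsub("-", " ", k, fixed = TRUE),
                          params$bond[[k]][1L], params$bond[[k]][2L]))
  for (k in names(params$angle))
    out <- c(out, sprintf("angle %s %.6g %.6g",
                          gsub("-", " ", k, fixed = TRUE),
                          params$angle[[k]][1L], params$angle[[k]][2L]))
  for (kind in c("torsion", "improper"))
    for (k in names(params[[kind]]))
      for (t in params[[kind]][[k]])
        out <- c(out, sprintf("%s %s %.6g %d %.6g", kind,
                              gsub("-", " ", k, fixed = TRUE),
                              t[1L], as.integer(t[2L]), t[3L]))
  for (k in names(params$lj))
    out <- c(out, sprintf("lj %s %.6g %.6g", k,
                          params$lj[[k]][1L], params$lj[[k]][2L]))
  for (k in names(params$charge))
    out <- c(out, sprintf("charge %s %.6g", k, params$charge[[k]]))
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# Energy + gradient.

accumulate_grad <- function(grad, idx, contrib) {
  s <- rowsum(contrib, idx)
  at <- as.integer(rownames(s))
  grad[at, ] <- grad[at, ] + s
  grad
}

# Minimum-image displacement matrix for an optional orthorhombic box.
pair_disp <- function(xyz, i, j, box) {
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  if (!is.null(box))
    d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
  d
}

#' Force-field energy and analytic gradient
#'
#' @param sys A `molsys` object (its `ff_type` and `charge` columns feed the
#'   parameter lookups).
#' @param topo A [perceive_topology()] result.
#' @param params A [parameter_set()].
#' @param settings A [nonbonded_settings()].
#' @return List with `energy` (class `energy_report`: bond, angle, torsion,
#'   improper, lj, coulomb, total in kcal/mol) and `gradient` (N x 3 matrix,
#'   kcal/mol/A).
#' @export
energy_and_gradient <- function(sys, topo, params,
                                settings = nonbonded_settings()) {
  xyz <- coords(sys)
  n <- nrow(xyz)
  types <- sys$atoms$ff_type
  q <- sys$atoms$charge
  box <- sys$box
  grad <- matrix(0, n, 3L)
  e_bond <- e_angle <- e_tors <- e_impr <- e_lj <- e_coul <- 0

  # --- bonds
  B <- topo$bonds
  if (nrow(B)) {
    pp <- vapply(seq_len(nrow(B)), function(r)
      lookup_bond_param(params, types[B[r, ]]), numeric(2L))
    k <- pp[1L, ]; r0 <- pp[2L, ]
    d <- pair_disp(xyz, B[, 1L], B[, 2L], box)
    r <- mrownorm(d)
    e_bond <- sum(k * (r - r0)^2)
    f <- 2 * k * (r - r0) / r
    grad <- accumulate_grad(grad, B[, 1L], d * f)
    grad <- accumulate_grad(grad, B[, 2L], -d * f)
  }

  # --- angles
  A <- topo$angles
  if (nrow(A)) {
    pp <- vapply(seq_len(nrow(A)), function(r)
      lookup_angle_param(params, types[A[r, ]]), numeric(2L))
    k <- pp[1L, ]; th0 <- pp[2L, ] * DEG2RAD
    u <- pair_disp(xyz, A[, 1L], A[, 2L], box)
    v <- pair_disp(xyz, A[, 3L], A[, 2L], box)
    nu <- mrownorm(u); nv <- mrownorm(v)
    uh <- u / nu; vh <- v / nv
    ct <- pmin(1, pmax(-1, rowSums(uh * vh)))
    th <- acos(ct)
    st <- pmax(sqrt(1 - ct^2), 1e-8)
    e_angle <- sum(k * (th - th0)^2)
    dEdth <- 2 * k * (th - th0)
    dthdi <- -(vh - ct * uh) / (nu * st)
    dthdk <- -(uh - ct * vh) / (nv * st)
    grad <- accumulate_grad(grad, A[, 1L], dEdth * dthdi)
    grad <- accumulate_grad(grad, A[, 3L], dEdth * dthdk)
    grad <- accumulate_grad(grad, A[, 2L], -dEdth * (dthdi + dthdk))
  }

  # --- proper torsions and impropers (same functional form)
  tors_part <- function(Tm, tbl, required) {
    if (!nrow(Tm)) return(list(e = 0))
    keep <- logical(nrow(Tm)); terms <- vector("list", nrow(Tm))
    for (r in seq_len(nrow(Tm))) {
      v <- lookup_torsion_param(tbl, types[Tm[r, ]])
      if (is.null(v)) {
        if (required) stop("missing torsion parameter for (",
                           param_key(types[Tm[r, ]]), ")")
        next
      }
      keep[r] <- TRUE; terms[[r]] <- v
    }
    Tm <- Tm[keep, , drop = FALSE]; terms <- terms[keep]
    if (!nrow(Tm)) return(list(e = 0))
    b1 <- pair_disp(xyz, Tm[, 2L], Tm[, 1L], box)
    b2 <- pair_disp(xyz, Tm[, 3L], Tm[, 2L], box)
    b3 <- pair_disp(xyz, Tm[, 4L], Tm[, 3L], box)
    n1 <- mcross(b1, b2); n2 <- mcross(b2, b3)
    nb2 <- mrownorm(b2)
    b2h <- b2 / nb2
    m1 <- mcross(n1, b2h)
    phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
    e <- 0
    dEdphi <- numeric(nrow(Tm))
    for (r in seq_len(nrow(Tm)))
      for (t in terms[[r]]) {
        g <- t[3L] * DEG2RAD
        e <- e + t[1L] * (1 + cos(t[2L] * phi[r] - g))
        dEdphi[r] <- dEdphi[r] - t[1L] * t[2L] * sin(t[2L] * phi[r] - g)
      }
    n1sq <- pmax(rowSums(n1 * n1), 1e-12)
    n2sq <- pmax(rowSums(n2 * n2), 1e-12)
    # signs follow the package's dihedral convention (cis = 0, measured via
    # atan2 with the n1 x b2-hat auxiliary), which negates the textbook form
    dphidi <- n1 * (nb2 / n1sq)
    dphidl <- -n2 * (nb2 / n2sq)
    c12 <- rowSums(b1 * b2) / nb2^2
    c32 <- rowSums(b3 * b2) / nb2^2
    dphidj <- (-c12 - 1) * dphidi + c32 * dphidl
    dphidk <- (-c32 - 1) * dphidl + c12 * dphidi
    g2 <- list(e = e,
               gi = dEdphi * dphidi, gj = dEdphi * dphidj,
               gk = dEdphi * dphidk, gl = dEdphi * dphidl, Tm = Tm)
    g2
  }
  tp <- tors_part(topo$torsions, params$torsion, required = TRUE)
  if (tp$e != 0 || !is.null(tp$Tm)) {
    e_tors <- tp$e
    if (!is.null(tp$Tm) && nrow(tp$Tm)) {
      grad <- accumulate_grad(grad, tp$Tm[, 1L], tp$gi)
      grad <- accumulate_grad(grad, tp$Tm[, 2L], tp$gj)
      grad <- accumulate_grad(grad, tp$Tm[, 3L], tp$gk)
      grad <- accumulate_grad(grad, tp$Tm[, 4L], tp$gl)
    }
  }
  ip <- tors_part(topo$impropers, params$improper, required = FALSE)
  if (!is.null(ip$Tm) && nrow(ip$Tm)) {
    e_impr <- ip$e
    grad <- accumulate_grad(grad, ip$Tm[, 1L], ip$gi)
    grad <- accumulate_grad(grad, ip$Tm[, 2L], ip$gj)
    grad <- accumulate_grad(grad, ip$Tm[, 3L], ip$gk)
    grad <- accumulate_grad(grad, ip$Tm[, 4L], ip$gl)
  }

  # --- nonbonded pairs (O(N^2) reference loop with cutoff)
  if (n >= 2L) {
    pi_ <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pj_ <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    key <- (pi_ - 1) * n + pj_
    ex <- c(if (nrow(topo$excl12)) (topo$excl12[, 1L] - 1) * n + topo$excl12[, 2L],
            if (nrow(topo$excl13)) (topo$excl13[, 1L] - 1) * n + topo$excl13[, 2L])
    s14 <- if (nrow(topo$scaled14))
      (topo$scaled14[, 1L] - 1) * n + topo$scaled14[, 2L] else integer(0)
    keep <- !(key %in% ex)
    pi_ <- pi_[keep]; pj_ <- pj_[keep]; key <- key[keep]
    is14 <- key %in% s14
    d <- pair_disp(xyz, pi_, pj_, box)
    r <- mrownorm(d)
    inc <- r <= settings$cutoff
    if (any(inc)) {
      pi_ <- pi_[inc]; pj_ <- pj_[inc]; d <- d[inc, , drop = FALSE]
      r <- r[inc]; is14 <- is14[inc]
      ljp <- vapply(unique(c(pi_, pj_)), function(i)
        lookup_lj_param(params, types[i]), numeric(2L))
      colnames(ljp) <- types[unique(c(pi_, pj_))]
      sig_i <- ljp[1L, types[pi_]]; sig_j <- ljp[1L, types[pj_]]
      eps_i <- ljp[2L, types[pi_]]; eps_j <- ljp[2L, types[pj_]]
      sig <- (sig_i + sig_j) / 2
      eps <- sqrt(eps_i * eps_j)
      sc_lj <- ifelse(is14, settings$scale14_lj, 1)
      sc_cl <- ifelse(is14, settings$scale14_coul, 1)
      sr6 <- (sig / r)^6
      e_lj <- sum(sc_lj * 4 * eps * (sr6^2 - sr6))
      dlj <- sc_lj * 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
      e_pair <- dsf_pair_energy(q[pi_], q[pj_], r, settings)
      e_coul <- sum(sc_cl * e_pair)
      dcl <- sc_cl * dsf_pair_dedr(q[pi_], q[pj_], r, settings)
      f <- (dlj + dcl) / r
      grad <- accumulate_grad(grad, pi_, d * f)
      grad <- accumulate_grad(grad, pj_, -d * f)
    }
  }

  comp <- c(bond = e_bond, angle = e_angle, torsion = e_tors,
            improper = e_impr, lj = e_lj, coulomb = e_coul)
  energy <- structure(as.list(c(comp, total = sum(comp))),
                      class = "energy_report")
  list(energy = energy, gradient = grad)
}

#' @export
print.energy_report <- function(x, ...) {
  for (k in names(x))
    cat(sprintf("%-9s %14.6f kcal/mol\n", k, x[[k]]))
  invisible(x)
}

#' Assign simple partial charges
#'
#' Electronegativity-equalisation over bonds: each bond moves
#' `s * (chi_j - chi_i)` of charge toward the more electronegative partner,
#' then each charge group is shifted uniformly so it sums to its formal
#' charge.  A stand-in scheme for force fields whose published charges are
#' derived by electrostatic-potential fitting.
#'
#' @param sys A `molsys` object with bonds.
#' @param formal Numeric vector of formal charges per charge group
#'   (default 0).
#' @param s Bond charge-transfer coefficient (e per electronegativity unit).
#' @return The system with `charge` filled in and groups marked neutralised.
#' @export
assign_simple_charges <- function(sys, formal = NULL, s = 0.16) {
  chi <- element_electronegativity(sys$atoms$element)
  qv <- numeric(nrow(sys$atoms))
  if (nrow(sys$bonds))
    for (r in seq_len(nrow(sys$bonds))) {
      i <- sys$bonds[r, 1L]; j <- sys$bonds[r, 2L]
      dq <- s * (chi[j] - chi[i])
      qv[i] <- qv[i] + dq
      qv[j] <- qv[j] - dq
    }
  groups <- sys$charge_groups
  if (is.null(formal)) formal <- rep(0, length(groups))
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    qv[ix] <- qv[ix] + (formal[g] - sum(qv[ix])) / length(ix)
  }
  sys$atoms$charge <- qv
  sys$neutralised <- TRUE
  sys
}
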