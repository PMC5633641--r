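toy <- make_toy_paramset()
nbs <- nonbonded_settings()

test_that("three-state enumeration yields 3^chi rotamers for all 20 residues", {
  chi_expected <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L,
                    GLN = 3L, GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L,
                    LEU = 2L, LYS = 4L, MET = 3L, PHE = 2L, PRO = 0L,
                    SER = 1L, THR = 1L, TRP = 2L, TYR = 2L, VAL = 1L)
  for (res in names(chi_expected)) {
    expect_equal(n_chi(res), chi_expected[[res]])
    rots <- enumerate_rotamers(res)
    expect_length(rots, 3L^chi_expected[[res]])
    expect_true(all(vapply(rots, length, 0L) == chi_expected[[res]]))
  }
  expect_length(enumerate_rotamers("LYS"), 81L)   # the largest case
  expect_length(enumerate_rotamers("GLY"), 1L)
  expect_length(enumerate_rotamers("SER"), 3L)
  expect_setequal(unlist(enumerate_rotamers("SER")), c(-60, 60, 180))
  expect_error(enumerate_rotamers("XYZ"), "unknown residue")
})

test_that("file-based rotamer libraries override the three-state scheme", {
  lib <- rotamer_library("SER -65\nSER 62\nLEU -60 175")
  expect_length(enumerate_rotamers("SER", lib), 2L)
  expect_equal(enumerate_rotamers("LEU", lib)[[1L]], c(-60, 175))
  expect_error(enumerate_rotamers("VAL", lib), "no entries")
})

test_that("applied rotamers re-measure exactly", {
  pa <- make_polyala(3L)
  expect_identical(coords(apply_rotamer(pa, 2L, numeric(0))), coords(pa))
  s <- mutate_residue(pa, 2L, "SER")
  s2 <- apply_rotamer(s, 2L, 180)
  expect_equal(backbone_torsions(s2)$chi1[2L], 180, tolerance = 1e-6)
  k <- mutate_residue(pa, 2L, "LYS")
  chi_target <- c(-60, 180, 60, 180)
  k2 <- apply_rotamer(k, 2L, chi_target)
  ix <- residue_atoms(k2, 2L)
  nm <- k2$atoms$name[ix]
  x <- coords(k2)
  quads <- list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ"))
  for (q in seq_along(quads)) {
    at <- vapply(quads[[q]], function(a) ix[nm == a][1L], 0L)
    expect_equal(mmforge:::wrap_angle(
      measure_dihedral(x[at[1L], ], x[at[2L], ], x[at[3L], ], x[at[4L], ]) -
        chi_target[q]), 0, tolerance = 1e-6)
  }
  expect_error(apply_rotamer(s, 2L, c(60, 60)), "needs 1 chi")
})

test_that("rotamer scans enumerate exhaustively and rank like a brute-force oracle", {
  pa <- make_polyala(4L)
  pa <- mutate_residue(pa, 2L, "SER")
  pa <- mutate_residue(pa, 3L, "SER")
  # single Ala residue: one trivially ranked combination
  sc1 <- rotamer_scan(pa, 1L)
  expect_equal(sc1$n_combinations, 1L)
  expect_equal(nrow(sc1$ranking), 1L)
  # two serines: 9 combinations, at most 10 kept
  tables <- synthetic_score_tables()
  sc <- rotamer_scan(pa, c(2L, 3L), tables = tables)
  expect_equal(sc$n_combinations, 9L)
  expect_lte(nrow(sc$ranking), 10L)
  expect_true(!is.unsorted(sc$ranking$score))
  # independent brute force: apply every combination, score, sort
  states <- c(-60, 60, 180)
  combos <- expand.grid(a = states, b = states)
  brute <- vapply(seq_len(nrow(combos)), function(k) {
    s2 <- apply_rotamer(pa, 2L, combos$a[k])
    s2 <- apply_rotamer(s2, 3L, combos$b[k])
    xyz <- coords(s2)
    scan <- c(residue_atoms(s2, 2L), residue_atoms(s2, 3L))
    env <- setdiff(seq_len(nrow(s2$atoms)), scan)
    ty <- s2$atoms$ff_type
    score_pose(xyz[env, ], xyz[scan, ], ty[env], ty[scan], tables)$total +
      score_pose(xyz[residue_atoms(s2, 2L), ], xyz[residue_atoms(s2, 3L), ],
                 ty[residue_atoms(s2, 2L)], ty[residue_atoms(s2, 3L)],
                 tables)$total
  }, 0)
  expect_equal(sc$ranking$score, sort(brute)[seq_len(nrow(sc$ranking))],
               tolerance = 1e-9)
  # top-scoring chi assignment agrees
  best <- combos[order(brute)[1L], ]
  expect_equal(unlist(sc$ranking$chi[[1L]]), c(best$a, best$b),
               ignore_attr = TRUE)
})

test_that("scan guards on selection size and combination count", {
  pa <- make_polyala(7L)
  expect_error(rotamer_scan(pa, 1:7), "between 1 and 6")
  pa2 <- make_polyala(4L)
  for (i in 1:4) pa2 <- mutate_residue(pa2, i, "LYS")
  expect_error(rotamer_scan(pa2, 1:4, max_combinations = 1000),
               "refusing")
})

test_that("force-field rescoring appends without reordering", {
  pa <- make_polyala(3L)
  pa <- mutate_residue(pa, 2L, "SER")
  topo <- perceive_topology(pa)
  sc <- rotamer_scan(pa, 2L, rescore = TRUE, topo = topo, params = toy)
  expect_true(!is.unsorted(sc$ranking$score))
  expect_true(all(is.finite(sc$ranking$rescore)))
  # the rescore values are genuine force-field energies
  s2 <- apply_rotamer(pa, 2L, unlist(sc$ranking$chi[[1L]]))
  expect_equal(sc$ranking$rescore[1L],
               energy_and_gradient(s2, topo, toy, nbs)$energy$total,
               tolerance = 1e-9)
})

test_that("riding protons complete methane, benzene and stripped peptides", {
  me <- place_missing_hydrogens(simple_system("C", c(0, 0, 0)))
  expect_equal(nrow(me$atoms), 5L)
  x <- coords(me)
  for (i in 2:4) for (j in (i + 1L):5L)
    expect_equal(measure_angle(x[i, ], x[1L, ], x[j, ]), 109.471,
                 tolerance = 0.01)
  expect_equal(sqrt(sum((x[2L, ] - x[1L, ])^2)), 1.09, tolerance = 1e-6)
  # benzene: ring-plane hydrogens
  n <- 6L
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  bz <- simple_system(rep("C", n),
                      cbind(1.39 / (2 * sin(pi / n)) * cos(ang),
                            1.39 / (2 * sin(pi / n)) * sin(ang), 0),
                      bonds = cbind(seq_len(n), c(2:n, 1L)))
  bzh <- place_missing_hydrogens(bz)
  expect_equal(nrow(bzh$atoms), 12L)
  xh <- coords(bzh)[7:12, ]
  expect_lt(max(abs(xh[, 3L])), 1.39 * sin(0.5 * pi / 180))  # < 0.5 deg
  # stripped polyalanine regains its exact hydrogen count
  pa <- make_polyala(3L)
  stripped <- remove_atoms(pa, which(pa$atoms$element == "H"))
  refilled <- place_missing_hydrogens(stripped)
  expect_equal(nrow(refilled$atoms), nrow(pa$atoms))
  expect_equal(sort(refilled$atoms$name), sort(pa$atoms$name))
  # X-H bond lengths match the templates
  hb <- refilled$bonds[refilled$atoms$element[refilled$bonds[, 2L]] == "H" |
                         refilled$atoms$element[refilled$bonds[, 1L]] == "H",
                       , drop = FALSE]
  xr <- coords(refilled)
  for (r in seq_len(nrow(hb))) {
    i <- hb[r, 1L]; j <- hb[r, 2L]
    h <- if (refilled$atoms$element[i] == "H") i else j
    p <- if (h == i) j else i
    expect_equal(sqrt(sum((xr[h, ] - xr[p, ])^2)),
                 mmforge:::xh_bond_length(refilled$atoms$element[p]),
                 tolerance = 1e-6)
  }
})

test_that("polar-hydrogen optimisation points a hydroxyl at its acceptor", {
  # methanol with an acceptor oxygen placed on the hydroxyl cone
  at <- data.frame(serial = 1:2, name = c("C", "O"),
                   element = c("C", "O"), ff_type = c("C", "O"),
                   charge = 0, x = c(0, 1.41), y = 0, z = 0,
                   residue_index = 1L, stringsAsFactors = FALSE)
  m <- place_missing_hydrogens(molecular_system(at,
                                                bonds = matrix(c(1L, 2L),
                                                               1L)))
  dirv <- c(cos(70.5 * pi / 180), sin(70.5 * pi / 180), 0)
  apos <- c(1.41, 0, 0) + 3.1 * dirv
  aw <- data.frame(serial = 100L, name = "O", element = "O", ff_type = "O",
                   charge = -0.4, x = apos[1L], y = apos[2L], z = apos[3L],
                   residue_index = 2L, stringsAsFactors = FALSE)
  res <- rbind(m$residues,
               data.frame(name = "HOH", chain = "A", seqnum = 2L,
                          icode = "", kind = "water", variant = ""))
  sys <- molecular_system(rbind(m$atoms, aw), res, m$bonds,
                          c(m$charge_groups, list(nrow(m$atoms) + 1L)))
  sys$atoms$charge[seq_len(nrow(m$atoms))] <-
    assign_simple_charges(m)$atoms$charge
  out <- optimize_polar_hydrogens(sys, perceive_topology(sys), toy, nbs)
  x <- coords(out$system)
  ho <- which(out$system$atoms$name == "H" &
                out$system$atoms$residue_index == 1L)
  expect_gt(measure_angle(x[2L, ], x[ho, ], x[nrow(x), ]), 150)
})

test_that("an isolated hydroxyl has no orientational preference", {
  at <- data.frame(serial = 1:2, name = c("C", "O"), element = c("C", "O"),
                   ff_type = c("C", "O"), charge = 0, x = c(0, 1.41),
                   y = 0, z = 0, residue_index = 1L,
                   stringsAsFactors = FALSE)
  m <- place_missing_hydrogens(molecular_system(at,
                                                bonds = matrix(c(1L, 2L),
                                                               1L)))
  m <- assign_simple_charges(m)
  out <- optimize_polar_hydrogens(m, perceive_topology(m), toy, nbs)
  tor <- out$decisions[out$decisions$type == "torsion", ]
  expect_true(nrow(tor) >= 1L)
})

test_that("side-chain flips are involutive and energy-ranked", {
  pa <- make_polyala(3L)
  for (res in c("GLN", "ASN", "HIS")) {
    s <- mutate_residue(pa, 2L, res)
    f1 <- mmforge:::flip_residue(s, 2L)
    f2 <- mmforge:::flip_residue(f1, 2L)
    expect_lt(max(abs(coords(f2) - coords(s))), 1e-9)
  }
  # the optimiser never returns a state worse than the flipped alternative
  s <- mutate_residue(pa, 2L, "GLN")
  topo <- perceive_topology(s)
  out <- optimize_polar_hydrogens(s, topo, toy, nbs)
  e_final <- energy_and_gradient(out$system, topo, toy, nbs)$energy$total
  e_flip <- energy_and_gradient(mmforge:::flip_residue(out$system, 2L),
                                topo, toy, nbs)$energy$total
  expect_lte(e_final, e_flip + 1e-6)
})

test_that("histidine variants carry the expected ring protons", {
  pa <- make_polyala(3L)
  h <- mutate_residue(pa, 2L, "HIS")
  v <- mmforge:::his_variants(h, 2L)
  names_of <- function(s) s$atoms$name[residue_atoms(s, 2L)]
  expect_true("HD1" %in% names_of(v$HID) && !("HE2" %in% names_of(v$HID)))
  expect_true("HE2" %in% names_of(v$HIE) && !("HD1" %in% names_of(v$HIE)))
  expect_true(all(c("HD1", "HE2") %in% names_of(v$HIP)))
})

test_that("sphere-sampled areas match closed forms and behave geometrically", {
  # isolated sphere: r_vdw(O) + probe
  s1 <- simple_system("O", c(0, 0, 0))
  expect_equal(sum(sasa(s1, probe = 1.4, n_points = 960L)),
               4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
  # two fully overlapping atoms expose one sphere in total
  s2 <- simple_system(c("O", "O"), rbind(c(0, 0, 0), c(0.05, 0, 0)))
  expect_equal(sum(sasa(s2, n_points = 960L)),
               4 * pi * (1.52 + 1.4)^2, tolerance = 0.01 * 4 * pi * 2.92^2)
  # total area grows monotonically with separation up to two full spheres
  seps <- c(0.5, 1.5, 2.5, 3.5, 4.5, 6.5)
  areas <- vapply(seps, function(d)
    sum(sasa(simple_system(c("O", "O"),
                           rbind(c(0, 0, 0), c(d, 0, 0))),
             n_points = 480L)), 0)
  expect_true(all(diff(areas) >= -1e-9))
  expect_equal(areas[length(areas)], 2 * 4 * pi * 2.92^2,
               tolerance = 0.01)
})

test_that("polar surface area selects exactly N, O and their hydrogens", {
  me <- place_missing_hydrogens(simple_system("C", c(0, 0, 0)))
  expect_equal(polar_surface_area(me), 0)
  w <- read_pdb(water_pdb_text)
  expect_equal(polar_surface_area(w), sum(sasa(w)), tolerance = 1e-9)
  # methanol: PSA = area of O plus its hydrogen only
  at <- data.frame(serial = 1:2, name = c("C", "O"), element = c("C", "O"),
                   ff_type = c("C", "O"), charge = 0, x = c(0, 1.41),
                   y = 0, z = 0, residue_index = 1L,
                   stringsAsFactors = FALSE)
  meoh <- place_missing_hydrogens(molecular_system(at,
                                                   bonds = matrix(c(1L, 2L),
                                                                  1L)))
  areas <- sasa(meoh)
  polar_idx <- which(meoh$atoms$name %in% c("O", "H"))
  expect_equal(polar_surface_area(meoh), sum(areas[polar_idx]),
               tolerance = 1e-9)
  expect_lte(polar_surface_area(meoh), sum(areas))
  # rigid-motion invariance
  m2 <- meoh
  coords(m2) <- sweep(coords(meoh) %*%
                        t(mmforge:::rotation_matrix(c(1, 2, 3), 0.8)),
                      2L, c(5, -1, 2), "+")
  # invariant up to the angular resolution of the sphere sampling
  expect_equal(polar_surface_area(m2), polar_surface_area(meoh),
               tolerance = 0.01)
})
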