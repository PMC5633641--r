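test_that("Z-matrix placement follows the origin/+x/+xy convention", {
  one <- zmatrix(data.frame(element = "C", bond_ref = NA_integer_,
                            angle_ref = NA_integer_,
                            dihedral_ref = NA_integer_, bond = NA_real_,
                            angle = NA_real_, dihedral = NA_real_))
  expect_equal(zmatrix_to_cartesian(one), matrix(0, 1L, 3L))
  z3 <- zmatrix(data.frame(
    element = c("O", "H", "H"),
    bond_ref = c(NA, 1L, 1L), angle_ref = c(NA, NA, 2L),
    dihedral_ref = NA_integer_,
    bond = c(NA, 1.5, 1.5), angle = c(NA, NA, 90), dihedral = NA_real_))
  xyz <- zmatrix_to_cartesian(z3)
  expect_equal(xyz[2L, ], c(1.5, 0, 0))
  expect_gt(xyz[3L, 2L], 0)                       # +y half plane
  expect_equal(vnorm <- sqrt(sum((xyz[3L, ] - xyz[1L, ])^2)), 1.5)
  expect_equal(measure_angle(xyz[3L, ], xyz[1L, ], xyz[2L, ]), 90)
})

test_that("a 180-degree dihedral yields a coplanar chain that remeasures exactly", {
  z <- zmatrix(data.frame(
    element = rep("C", 4L),
    bond_ref = c(NA, 1L, 2L, 3L), angle_ref = c(NA, NA, 1L, 2L),
    dihedral_ref = c(NA, NA, NA, 1L),
    bond = c(NA, 1.5, 1.5, 1.5), angle = c(NA, NA, 111, 111),
    dihedral = c(NA, NA, NA, 180)))
  xyz <- zmatrix_to_cartesian(z)
  expect_lt(max(abs(xyz[, 3L])), 1e-12)           # coplanar (z = 0 frame)
  expect_equal(measure_dihedral(xyz[4L, ], xyz[3L, ], xyz[2L, ], xyz[1L, ]),
               180)
})

test_that("degenerate bond angles are rejected", {
  z <- zmatrix(data.frame(
    element = rep("C", 4L),
    bond_ref = c(NA, 1L, 2L, 3L), angle_ref = c(NA, NA, 1L, 2L),
    dihedral_ref = c(NA, NA, NA, 1L),
    bond = c(NA, 1.5, 1.5, 1.5), angle = c(NA, NA, 111, 180),
    dihedral = c(NA, NA, NA, 60)))
  expect_error(zmatrix_to_cartesian(z), "degenerate")
  lin <- simple_system(rep("C", 3L),
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)))
  expect_error(cartesian_to_zmatrix(lin), "degenerate|collinear")
})

test_that("random valid Z-matrices round trip through Cartesians below 1e-8 A", {
  for (seed in c(2L, 5L, 8L, 13L)) {
    z <- random_zmatrix(20L, seed)
    xyz <- zmatrix_to_cartesian(z)
    sys <- simple_system(z$rows$element, xyz)
    z2 <- cartesian_to_zmatrix(sys)
    expect_rigid_equal(zmatrix_to_cartesian(z2), xyz, tol = 1e-8)
  }
})

test_that("dihedral measurement follows the IUPAC convention and its symmetries", {
  expect_equal(measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0)), 0)           # cis
  expect_equal(measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, -1, 0)), 180)        # trans
  # right-angle case against the explicit atan2 formula
  p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  bh <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * bh[3] - n1[3] * bh[2], n1[3] * bh[1] - n1[1] * bh[3],
          n1[1] * bh[2] - n1[2] * bh[1])
  ref <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  expect_equal(measure_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), ref)
  expect_equal(abs(ref), 90)
  # reversal antisymmetry and rigid-motion invariance on random quads
  set.seed(31)
  for (k in 1:5) {
    q <- matrix(stats::rnorm(12), 4L, 3L) * 2
    d1 <- measure_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    d2 <- measure_dihedral(q[4, ], q[3, ], q[2, ], q[1, ])
    expect_equal(d1, d2)   # dihedrals are invariant under order reversal
    R <- mmforge:::rotation_matrix(stats::rnorm(3L), stats::runif(1L, 0, pi))
    q2 <- sweep(q %*% t(R), 2L, c(3, -1, 2), "+")
    expect_equal(measure_dihedral(q2[1, ], q2[2, ], q2[3, ], q2[4, ]), d1,
                 tolerance = 1e-9)
  }
  expect_error(measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "collinear")
})

test_that("set_torsion hits the target, moves only one side and preserves bonds", {
  bu <- simple_system(rep("C", 4L),
                      rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                            c(1.4, 0.9, 0.6)),
                      bonds = cbind(1:3, 2:4))
  s60 <- set_torsion(bu, c(1L, 2L, 3L, 4L), 60)
  x <- coords(s60)
  expect_equal(measure_dihedral(x[1, ], x[2, ], x[3, ], x[4, ]), 60,
               tolerance = 1e-6)
  # setting the current value is the identity
  cur <- measure_dihedral(x[1, ], x[2, ], x[3, ], x[4, ])
  expect_identical(coords(set_torsion(s60, c(1L, 2L, 3L, 4L), cur)), x)
  # bond lengths unchanged
  blen <- function(s) {
    xy <- coords(s)
    sqrt(rowSums((xy[s$bonds[, 1L], ] - xy[s$bonds[, 2L], ])^2))
  }
  expect_lt(max(abs(blen(s60) - blen(bu))), 1e-9)
  # phi sweep on a longer chain: every target reproduced; the larger side
  # stays put (atoms 1..4 of 7 when rotating the 5-7 tail)
  ch <- random_chain_system(7L, seed = 6L)
  for (tgt in seq(-180, 150, by = 30)) {
    s2 <- set_torsion(ch, c(3L, 4L, 5L, 6L), tgt)
    x2 <- coords(s2)
    expect_equal(mmforge:::wrap_angle(
      measure_dihedral(x2[3, ], x2[4, ], x2[5, ], x2[6, ]) - tgt), 0,
      tolerance = 1e-6)
    expect_identical(x2[1:4, ], coords(ch)[1:4, ])
  }
  # pairwise distances within each rigid side are preserved (isometry)
  s3 <- set_torsion(ch, c(3L, 4L, 5L, 6L), 77)
  d_before <- as.matrix(dist(coords(ch)))
  d_after <- as.matrix(dist(coords(s3)))
  expect_lt(max(abs(d_after[5:7, 5:7] - d_before[5:7, 5:7])), 1e-9)
  expect_lt(max(abs(d_after[1:4, 1:4] - d_before[1:4, 1:4])), 1e-9)
})

test_that("ring torsions are refused", {
  n <- 6L
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  ring <- simple_system(rep("C", n),
                        cbind(1.53 / (2 * sin(pi / n)) * cos(ang),
                              1.53 / (2 * sin(pi / n)) * sin(ang), 0),
                        bonds = cbind(seq_len(n), c(2:n, 1L)))
  expect_error(set_torsion(ring, c(1L, 2L, 3L, 4L), 30), "ring")
})

test_that("mutation keeps the backbone and rebuilds template side chains", {
  pa <- make_polyala(3L)
  bb_xyz <- function(s) coords(s)[mmforge:::find_backbone(s, 2L), ]
  g <- mutate_residue(pa, 2L, "GLY")
  expect_equal(sort(g$atoms$name[residue_atoms(g, 2L)]),
               sort(c("N", "CA", "C", "O", "H", "HA1", "HA2")))
  expect_identical(bb_xyz(g), bb_xyz(pa))
  back <- mutate_residue(g, 2L, "ALA")
  expect_identical(bb_xyz(back), bb_xyz(pa))
  f <- mutate_residue(pa, 2L, "PHE")
  expect_equal(round(backbone_torsions(f)$chi1[2L]), -60)  # first rotamer
  expect_error(mutate_residue(pa, 2L, "XXX"), "unknown residue")
})

test_that("Ramachandran classification is piecewise constant with known anchors", {
  expect_equal(classify_ramachandran(-60, -45), "favoured")
  expect_equal(classify_ramachandran(0, 0), "outlier")
  expect_equal(classify_ramachandran(-120, 130), "favoured")   # beta
  expect_equal(classify_ramachandran(60, 45), "allowed")       # left helix
  expect_equal(classify_ramachandran(-60, -45),
               classify_ramachandran(-60.01, -45.01))
  expect_equal(classify_ramachandran(0, 0), classify_ramachandran(0.01, 0.01))
})

test_that("Z-matrix text files round trip", {
  z <- random_zmatrix(8L, seed = 17L)
  z2 <- read_zmatrix(write_zmatrix(z))
  expect_equal(z2$rows$bond, z$rows$bond, tolerance = 1e-6)
  expect_equal(z2$rows$angle, z$rows$angle, tolerance = 1e-6)
  expect_equal(z2$rows$dihedral, z$rows$dihedral, tolerance = 1e-6)
  expect_identical(z2$rows$bond_ref, z$rows$bond_ref)
  expect_error(read_zmatrix(""), "empty")
  expect_error(read_zmatrix("C\nH 1"), "parse error")
})

test_that("backbone torsions report the built conformation", {
  bt <- backbone_torsions(make_polyala(4L))
  expect_equal(bt$phi[2:4], rep(-60, 3L), tolerance = 1e-6)
  expect_equal(bt$psi[1:3], rep(-45, 3L), tolerance = 1e-6)
  expect_equal(bt$omega[2:4], rep(180, 3L), tolerance = 1e-6)
  expect_true(is.na(bt$phi[1L]) && is.na(bt$psi[4L]))
})
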