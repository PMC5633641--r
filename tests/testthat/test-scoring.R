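test_that("Boltzmann inversion reproduces closed-form ratios", {
  edges <- seq(0, 1, by = 0.5)
  # equal distributions invert to zero everywhere
  h <- distance_histogram(c("A", "B"), edges, c(10, 10))
  r <- distance_histogram(c("A", "B"), edges, c(10, 10))
  expect_equal(pmf_from_histogram(h, r)$energies, c(0, 0))
  # observed/reference ratio e^-1 in the first bin, anchored at the last:
  # e = +kB T = 0.6 kcal/mol at T = 0.6 / kB
  T <- 0.6 / 0.0019872041
  h2 <- distance_histogram(c("A", "B"), edges, c(exp(-1), 1))
  r2 <- distance_histogram(c("A", "B"), edges, c(1, 1))
  expect_equal(pmf_from_histogram(h2, r2, T = T)$energies[1L], 0.6,
               tolerance = 1e-9)
  expect_error(pmf_from_histogram(h2, distance_histogram(c("A", "B"), edges,
                                                         c(0, 0))),
               "zero everywhere")
})

test_that("inversion recovers a known potential from its own Boltzmann sample", {
  U <- function(r) 2 * ((2.5 / r)^8 - 2 * (2.5 / r)^4) +
    0.5 * exp(-(r - 5)^2)
  hs <- make_synthetic_histograms(U, n_samples = 60000L, seed = 7L)
  tab <- pmf_from_histogram(hs$observed, hs$reference, T = 300)
  edges <- tab$bin_edges
  kT <- 0.0019872041 * 300
  # the estimator converges to the bin-integrated PMF: e_bin =
  # -kT ln( int_bin exp(-U/kT) r^2 dr / int_bin r^2 dr ), anchored at the
  # cutoff bin -- integrate it numerically as the exact oracle
  nb <- length(edges) - 1L
  truth <- vapply(seq_len(nb), function(k) {
    num <- stats::integrate(function(r) exp(-U(r) / kT) * r^2,
                            edges[k], edges[k + 1L])$value
    den <- stats::integrate(function(r) r^2, edges[k], edges[k + 1L])$value
    -kT * log(num / den)
  }, 0)
  truth <- truth - truth[nb]
  counts <- hs$observed$counts
  sel <- counts >= 25 & truth < 2.5          # below the repulsive cap
  # 3 sigma multinomial sampling error, anchor-bin noise included
  sigma <- kT * sqrt(1 / pmax(counts, 1) + 1 / counts[length(counts)])
  expect_true(all(abs(tab$energies - truth)[sel] <= 3 * sigma[sel]))
})

test_that("recovery error shrinks as the sample grows", {
  U <- function(r) 1.5 * ((2.8 / r)^8 - 2 * (2.8 / r)^4)
  kT <- 0.0019872041 * 300
  binned_truth <- function(edges) {
    nb <- length(edges) - 1L
    tr <- vapply(seq_len(nb), function(k) {
      num <- stats::integrate(function(r) exp(-U(r) / kT) * r^2,
                              edges[k], edges[k + 1L])$value
      den <- stats::integrate(function(r) r^2, edges[k],
                              edges[k + 1L])$value
      -kT * log(num / den)
    }, 0)
    tr - tr[nb]
  }
  err_at <- function(n) {
    hs <- make_synthetic_histograms(U, n_samples = n, seed = 11L)
    tab <- pmf_from_histogram(hs$observed, hs$reference, T = 300)
    truth <- binned_truth(tab$bin_edges)
    sel <- hs$observed$counts >= 25 & truth < 2.5
    sqrt(mean((tab$energies - truth)[sel]^2))
  }
  errs <- c(err_at(4000L), err_at(16000L), err_at(64000L))
  expect_lt(errs[3L], errs[1L])
})

test_that("distance-scaled reference mode weights bins by r^exponent", {
  edges <- seq(0, 2, by = 1)
  centres <- c(0.5, 1.5)
  h <- distance_histogram(c("A", "B"), edges, centres^1.61)
  tab <- pmf_from_histogram(h, NULL, exponent = 1.61)
  expect_equal(tab$energies, c(0, 0))           # matches its own reference
  expect_match(tab$reference_mode, "distance_scaled")
})

test_that("pose scores equal a brute-force double loop with interpolation", {
  tables <- synthetic_score_tables()
  set.seed(19)
  px <- matrix(stats::rnorm(30), 10L, 3L) * 3
  lx <- matrix(stats::rnorm(15), 5L, 3L)
  pt <- sample(c("C", "N", "O"), 10L, replace = TRUE)
  lt <- sample(c("C", "O", "H"), 5L, replace = TRUE)
  sc <- score_pose(px, lx, pt, lt, tables)
  brute <- 0
  for (i in 1:10) for (j in 1:5) {
    r <- sqrt(sum((px[i, ] - lx[j, ])^2))
    tb <- tables[[table_key(pt[i], lt[j])]]
    cent <- (tb$bin_edges[-1L] + tb$bin_edges[-length(tb$bin_edges)]) / 2
    if (r >= tb$cutoff) next
    k <- findInterval(r, cent)
    v <- if (k == 0L) tb$energies[1L]
    else if (k >= length(cent)) tb$energies[length(cent)]
    else tb$energies[k] + (tb$energies[k + 1L] - tb$energies[k]) *
      (r - cent[k]) / (cent[k + 1L] - cent[k])
    brute <- brute + v
  }
  expect_equal(sc$total, brute, tolerance = 1e-10)
  expect_equal(sum(sc$pairs$e), sc$total, tolerance = 1e-10)
})

test_that("pose scoring honours cutoffs, single lookups and missing tables", {
  # custom one-pair table with value -1.5 at 3.0 A
  edges <- seq(0, 12, by = 0.2)
  centres <- (edges[-1L] + edges[-length(edges)]) / 2
  e <- numeric(length(centres))
  e[centres > 2.8 & centres < 3.2] <- -1.5
  tab <- structure(list(type_pair = c("C", "C"), bin_edges = edges,
                        energies = e, cutoff = 12,
                        reference_mode = "bulk_ratio"),
                   class = "pair_potential")
  sc <- score_pose(matrix(c(0, 0, 0), 1L), matrix(c(3.0, 0, 0), 1L),
                   "C", "C", list("C-C" = tab))
  expect_equal(sc$total, -1.5, tolerance = 1e-12)
  # beyond cutoff: zero
  sc0 <- score_pose(matrix(c(0, 0, 0), 1L), matrix(c(20, 0, 0), 1L),
                    "C", "C", list("C-C" = tab))
  expect_equal(sc0$total, 0)
  expect_warning(score_pose(matrix(0, 1L, 3L), matrix(c(3, 0, 0), 1L),
                            "C", "ZZ", list("C-C" = tab)),
                 "no pair-potential table")
  expect_error(score_pose(matrix(0, 1L, 3L), matrix(c(3, 0, 0), 1L),
                          "C", "ZZ", list("C-C" = tab),
                          warn_missing = FALSE),
               "no pair-potential table")
})

test_that("pose scores are invariant under a joint rigid transform", {
  tables <- synthetic_score_tables()
  set.seed(23)
  px <- matrix(stats::rnorm(24), 8L, 3L) * 2.5
  lx <- matrix(stats::rnorm(9), 3L, 3L)
  pt <- rep(c("C", "O"), length.out = 8L)
  lt <- c("N", "C", "O")
  s1 <- score_pose(px, lx, pt, lt, tables)$total
  R <- mmforge:::rotation_matrix(c(0.3, 1, -2), 1.3)
  tv <- c(4, -7, 2)
  s2 <- score_pose(sweep(px %*% t(R), 2L, tv, "+"),
                   sweep(lx %*% t(R), 2L, tv, "+"), pt, lt, tables)$total
  expect_equal(s2, s1, tolerance = 1e-9)
})

test_that("pose transforms are rigid and validated", {
  set.seed(29)
  lx <- matrix(stats::rnorm(15), 5L, 3L)
  expect_equal(transform_pose(lx), lx)
  moved <- transform_pose(transform_pose(lx, translation = c(1, 0, 0)),
                          translation = c(-1, 0, 0))
  expect_lt(max(abs(moved - lx)), 1e-12)
  R <- mmforge:::rotation_matrix(c(1, 1, 1), 0.7)
  rot <- transform_pose(lx, rotation = R)
  expect_lt(max(abs(as.matrix(dist(rot)) - as.matrix(dist(lx)))), 1e-12)
  expect_error(transform_pose(lx, rotation = diag(c(1, 1, -1))), "proper")
})

test_that("three-point alignment meets its geometric contract", {
  set.seed(37)
  mob <- matrix(stats::rnorm(24), 8L, 3L) * 2
  # identical molecule, same triplet: identity
  out0 <- align_three_point(mob, mob, 1:3, 1:3)
  expect_lt(max(abs(out0 - mob)), 1e-10)
  # rotated + translated copy: exact recovery
  R <- mmforge:::rotation_matrix(c(2, -1, 0.5), 1.9)
  tar <- sweep(mob %*% t(R), 2L, c(3, 5, -2), "+")
  out <- align_three_point(mob, tar, 1:3, 1:3)
  expect_lt(sqrt(mean(rowSums((out - tar)^2))), 1e-10)
  # different molecule sharing a motif: constraint geometry only
  mob2 <- rbind(mob[1:3, ], matrix(stats::rnorm(9), 3L, 3L))
  out2 <- align_three_point(mob2, tar, 1:3, 1:3)
  expect_lt(sqrt(sum((out2[1L, ] - tar[1L, ])^2)), 1e-10)
  u_m <- out2[2L, ] - out2[1L, ]
  u_t <- tar[2L, ] - tar[1L, ]
  cosang <- sum(u_m * u_t) / sqrt(sum(u_m^2) * sum(u_t^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  # atom 3 in the target plane, same side
  n_t <- mmforge:::vcross(tar[2L, ] - tar[1L, ], tar[3L, ] - tar[1L, ])
  expect_lt(abs(sum((out2[3L, ] - tar[1L, ]) * n_t)) / sqrt(sum(n_t^2)),
            1e-9)
  expect_gt(sum(mmforge:::vcross(out2[2L, ] - out2[1L, ],
                                 out2[3L, ] - out2[1L, ]) * n_t), 0)
  # rigidity and idempotence
  expect_lt(max(abs(as.matrix(dist(out2)) - as.matrix(dist(mob2)))), 1e-9)
  twice <- align_three_point(out2, tar, 1:3, 1:3)
  expect_lt(max(abs(twice - out2)), 1e-9)
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_error(align_three_point(coll, tar, 1:3, 1:3), "collinear")
})

test_that("pair-potential tables round trip through their file format", {
  tab <- synthetic_score_tables()[["C-O"]]
  t2 <- read_pair_potential(write_pair_potential(tab))
  expect_equal(t2$energies, tab$energies, tolerance = 1e-7)
  expect_equal(t2$bin_edges, tab$bin_edges, tolerance = 1e-6)
  expect_equal(t2$type_pair, tab$type_pair)
  expect_equal(t2$cutoff, tab$cutoff)
})
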