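toy <- make_toy_paramset()
nbs <- nonbonded_settings()

test_that("both optimisers solve a 2-D quadratic bowl exactly", {
  fn <- function(x) (x[1L] - 1)^2 + 2 * (x[2L] - 2)^2
  gr <- function(x) c(2 * (x[1L] - 1), 4 * (x[2L] - 2))
  for (opt in list(opt_lbfgs, opt_cg_powell_beale)) {
    res <- opt(fn, gr, c(5, -3), grad_tol = 1e-8, max_iter = 200L)
    expect_true(res$converged)
    expect_equal(res$x, c(1, 2), tolerance = 1e-6)
  }
})

test_that("a stretched harmonic diatomic relaxes to its equilibrium length", {
  di <- simple_system(c("C", "C"), rbind(c(0, 0, 0), c(1.9, 0, 0)),
                      bonds = matrix(c(1L, 2L), 1L))
  topo <- perceive_topology(di)
  for (m in c("lbfgs", "cg_powell_beale")) {
    res <- minimize(di, topo, toy,
                    options = minimizer_options(m, grad_tol = 1e-8))
    r <- sqrt(sum(diff(coords(res$system))^2))
    expect_equal(r, toy$bond[["C-C"]][2L], tolerance = 1e-6)
    expect_true(res$converged)
    expect_lt(res$avg_grad, 1e-8)       # converged implies below tolerance
  }
})

test_that("conjugate gradients finish an n-dimensional quadratic in n iterations", {
  set.seed(11)
  n <- 9L
  M <- matrix(stats::rnorm(n * n), n)
  A <- crossprod(M) + diag(n) * 0.5
  b <- stats::rnorm(n)
  res <- opt_cg_powell_beale(function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x),
                             function(x) as.vector(A %*% x) - b,
                             rep(0, n), grad_tol = 1e-9, max_iter = 50L)
  expect_lte(res$iterations, n)
  expect_lt(max(abs(res$x - solve(A, b))), 1e-8)
  # L-BFGS agrees with the analytic minimiser too
  res2 <- opt_lbfgs(function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x),
                    function(x) as.vector(A %*% x) - b,
                    rep(0, n), grad_tol = 1e-10, max_iter = 200L)
  expect_lt(max(abs(res2$x - solve(A, b))), 1e-7)
})

test_that("minimisation agrees with an independent quasi-Newton implementation", {
  sys <- random_chain_system(6L, seed = 23L)
  topo <- perceive_topology(sys)
  res <- minimize(sys, topo, toy,
                  options = minimizer_options("lbfgs", grad_tol = 1e-6,
                                              max_iter = 2000L))
  sys_w <- sys
  x0 <- as.vector(t(coords(sys)))
  fn <- function(x) {
    coords(sys_w) <- matrix(x, ncol = 3L, byrow = TRUE)
    energy_and_gradient(sys_w, topo, toy, nbs)$energy$total
  }
  gr <- function(x) {
    coords(sys_w) <- matrix(x, ncol = 3L, byrow = TRUE)
    as.vector(t(energy_and_gradient(sys_w, topo, toy, nbs)$gradient))
  }
  ref <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 2000L, factr = 10))
  expect_equal(res$energy, ref$value, tolerance = 1e-5)
})

test_that("accepted steps decrease the energy monotonically", {
  sys <- make_polyala(2L)
  topo <- perceive_topology(sys)
  for (m in c("lbfgs", "cg_powell_beale")) {
    res <- minimize(sys, topo, toy,
                    options = minimizer_options(m, grad_tol = 0.2,
                                                max_iter = 300L))
    expect_true(all(diff(res$trace) <= 1e-9))
  }
})

test_that("frozen atoms stay bit-identical through minimisation", {
  sys <- make_polyala(2L)
  topo <- perceive_topology(sys)
  frozen <- residue_atoms(sys, 1L)
  res <- minimize(sys, topo, toy,
                  options = minimizer_options("lbfgs", grad_tol = 0.3,
                                              frozen = frozen))
  expect_identical(coords(res$system)[frozen, ], coords(sys)[frozen, ])
  expect_error(minimize(sys, topo, toy,
                        options = minimizer_options(
                          frozen = seq_len(nrow(sys$atoms)))),
               "empty free set")
})

test_that("partial complex optimisation freezes the receptor exactly", {
  tp <- make_toy_pocket(1L)
  topo <- perceive_topology(tp)
  lig <- attr(tp, "ligand_atoms")
  rec <- attr(tp, "receptor_atoms")
  e0 <- energy_and_gradient(tp, topo, toy, nbs)$energy$total
  res <- minimize_complex(tp, topo, toy, nbs, ligand = lig,
                          options = minimizer_options("lbfgs",
                                                      grad_tol = 0.1))
  expect_lt(res$energy, e0)
  expect_identical(coords(res$system)[rec, ], coords(tp)[rec, ])
  expect_lt(res$avg_grad, 0.1)
  # all atoms flexible reduces to plain minimize
  res_all <- minimize_complex(tp, topo, toy, nbs, ligand = lig,
                              flexible_residues = 1L,
                              options = minimizer_options("lbfgs",
                                                          grad_tol = 0.2))
  res_plain <- minimize(tp, topo, toy, nbs,
                        options = minimizer_options("lbfgs",
                                                    grad_tol = 0.2))
  expect_equal(res_all$energy, res_plain$energy, tolerance = 1e-9)
})

test_that("heavy-atom RMSD matches its closed forms and an explicit oracle", {
  sys <- make_polyala(2L)
  expect_equal(rmsd_heavy(sys, sys), 0)
  shifted <- sys
  xyz <- coords(sys)
  xyz[, 1L] <- xyz[, 1L] + 1
  coords(shifted) <- xyz
  expect_equal(rmsd_heavy(sys, shifted), 1.0, tolerance = 1e-12)
  set.seed(77)
  pert <- sys
  d <- matrix(stats::rnorm(3L * nrow(xyz), sd = 0.3), ncol = 3L)
  coords(pert) <- coords(sys) + d
  heavy <- sys$atoms$element != "H"
  expect_equal(rmsd_heavy(sys, pert),
               sqrt(mean(rowSums(d[heavy, , drop = FALSE]^2))),
               tolerance = 1e-12)
  bad <- simple_system("C", c(0, 0, 0))
  expect_error(rmsd_heavy(sys, bad), "mismatch")
})

test_that("the Powell restart fires on an ill-conditioned problem yet converges", {
  # banana-style valley: strongly non-quadratic, guaranteed conjugacy loss
  fn <- function(x) 100 * (x[2L] - x[1L]^2)^2 + (1 - x[1L])^2
  gr <- function(x) c(-400 * x[1L] * (x[2L] - x[1L]^2) - 2 * (1 - x[1L]),
                      200 * (x[2L] - x[1L]^2))
  res <- opt_cg_powell_beale(fn, gr, c(-1.2, 1), grad_tol = 1e-7,
                             max_iter = 5000L)
  expect_true(res$converged)
  expect_gt(res$restarts, 0L)
  expect_equal(res$x, c(1, 1), tolerance = 1e-4)
})

test_that("default method selection follows system size", {
  small <- make_polyala(2L)
  topo <- perceive_topology(small)
  res <- minimize(small, topo, toy,
                  options = minimizer_options("auto", grad_tol = 2,
                                              max_iter = 5L))
  expect_equal(res$method, "cg_powell_beale")
})
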