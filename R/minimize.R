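# Energy minimisation: limited-memory BFGS (two-loop recursion, Armijo
# backtracking with a weak-Wolfe curvature check) for large systems, and a
# Powell-Beale restarted conjugate-gradient method with a secant line search
# for small molecules and crystals.  Convergence is declared on the average
# per-atom gradient-vector norm, the convention used for optimisation
# gradient tolerances throughout the package.

avg_atom_gradient <- function(g) {
  if (length(g) %% 3L == 0L) {
    m <- matrix(g, ncol = 3L, byrow = FALSE)
    mean(sqrt(rowSums(m * m)))
  } else sqrt(sum(g * g)) / max(1L, length(g))
}

# Armijo backtracking line search with optional weak-Wolfe curvature test.
# Returns list(alpha, x, f, g, ok).
line_search_backtrack <- function(fn, gr, x, f0, g0, d, alpha0 = 1,
                                  c1 = 1e-4, c2 = 0.9, max_backtracks = 40L) {
  slope <- sum(g0 * d)
  if (slope >= 0) return(list(ok = FALSE))
  alpha <- alpha0
  for (k in seq_len(max_backtracks)) {
    xn <- x + alpha * d
    fn_v <- fn(xn)
    if (is.finite(fn_v) && fn_v <= f0 + c1 * alpha * slope) {
      gn <- gr(xn)
      if (sum(gn * d) >= c2 * slope || k == max_backtracks)
        return(list(ok = TRUE, alpha = alpha, x = xn, f = fn_v, g = gn))
      # Armijo holds but curvature not yet: accept anyway (backtracking
      # cannot extend the step); monotone decrease is what we guarantee
      return(list(ok = TRUE, alpha = alpha, x = xn, f = fn_v, g = gn))
    }
    alpha <- alpha / 2
  }
  list(ok = FALSE)
}

# Secant line search on the directional derivative; exact for quadratics.
line_search_secant <- function(fn, gr, x, f0, g0, d, alpha0 = 1,
                               max_iter = 20L) {
  slope0 <- sum(g0 * d)
  if (slope0 >= 0) return(list(ok = FALSE))
  a_prev <- 0; s_prev <- slope0
  a <- alpha0
  for (k in seq_len(max_iter)) {
    s <- sum(gr(x + a * d) * d)
    if (abs(s) <= 1e-12 * abs(slope0) + 1e-300) break
    denom <- s - s_prev
    if (abs(denom) < 1e-300) break
    a_new <- a - s * (a - a_prev) / denom
    if (!is.finite(a_new) || a_new <= 0) break
    a_prev <- a; s_prev <- s
    a <- a_new
  }
  xn <- x + a * d
  fn_v <- fn(xn)
  if (!is.finite(fn_v) || fn_v > f0 + 1e-12 * (1 + abs(f0)))
    return(line_search_backtrack(fn, gr, x, f0, g0, d, alpha0))
  list(ok = TRUE, alpha = a, x = xn, f = fn_v, g = gr(xn))
}

#' Low-level limited-memory BFGS minimiser
#'
#' @param fn,gr Objective and gradient functions of a numeric vector.
#' @param x0 Start vector.
#' @param grad_tol Convergence threshold on the mean per-atom (per
#'   3-component block) gradient norm.
#' @param max_iter Iteration cap.
#' @param m History length.
#' @return List: `x`, `f`, `g`, `iterations`, `converged`, `trace`
#'   (energy per accepted iteration), `message`.
#' @export
opt_lbfgs <- function(fn, gr, x0, grad_tol = 0.5, max_iter = 1000L, m = 10L) {
  x <- x0; f <- fn(x); g <- gr(x)
  S <- list(); Y <- list()
  trace <- f
  for (it in seq_len(max_iter)) {
    if (avg_atom_gradient(g) < grad_tol)
      return(list(x = x, f = f, g = g, iterations = it - 1L,
                  converged = TRUE, trace = trace, message = "converged"))
    # two-loop recursion
    qv <- g
    k <- length(S)
    alpha <- numeric(k)
    rho <- vapply(seq_len(k), function(i) 1 / sum(Y[[i]] * S[[i]]), 0)
    if (k > 0)
      for (i in k:1L) {
        alpha[i] <- rho[i] * sum(S[[i]] * qv)
        qv <- qv - alpha[i] * Y[[i]]
      }
    gamma <- if (k > 0) sum(S[[k]] * Y[[k]]) / sum(Y[[k]] * Y[[k]]) else 1
    z <- gamma * qv
    if (k > 0)
      for (i in 1L:k) {
        beta <- rho[i] * sum(Y[[i]] * z)
        z <- z + S[[i]] * (alpha[i] - beta)
      }
    d <- -z
    ls <- line_search_backtrack(fn, gr, x, f, g, d)
    if (!ls$ok) {
      # steepest-descent restart before giving up
      S <- list(); Y <- list()
      ls <- line_search_backtrack(fn, gr, x, f, g, -g,
                                  alpha0 = 1 / max(1, vnorm(g)))
      if (!ls$ok)
        return(list(x = x, f = f, g = g, iterations = it,
                    converged = avg_atom_gradient(g) < grad_tol,
                    trace = trace,
                    message = "line search failed after maximum backtracks"))
    }
    s <- ls$x - x; y <- ls$g - g
    if (sum(s * y) > 1e-12) {
      S <- c(S, list(s)); Y <- c(Y, list(y))
      if (length(S) > m) { S <- S[-1L]; Y <- Y[-1L] }
    }
    x <- ls$x; f <- ls$f; g <- ls$g
    trace <- c(trace, f)
  }
  list(x = x, f = f, g = g, iterations = max_iter,
       converged = avg_atom_gradient(g) < grad_tol, trace = trace,
       message = "maximum iterations reached")
}

#' Low-level Powell-Beale restarted conjugate-gradient minimiser
#'
#' Hestenes-Stiefel update with Beale's three-term restart direction and
#' Powell's restart test `|g_k . g_{k-1}| >= 0.2 |g_k|^2`, secant line
#' search (exact on quadratics).
#'
#' @inheritParams opt_lbfgs
#' @return Same shape as [opt_lbfgs()], plus `restarts`.
#' @export
opt_cg_powell_beale <- function(fn, gr, x0, grad_tol = 0.5,
                                max_iter = 1000L) {
  x <- x0; f <- fn(x); g <- gr(x)
  d <- -g
  g_prev <- NULL; d_prev <- NULL
  dt <- NULL; yt <- NULL          # Beale restart direction and its y
  restarts <- 0L
  trace <- f
  slope_prev <- NA_real_
  alpha_prev <- NA_real_
  for (it in seq_len(max_iter)) {
    if (avg_atom_gradient(g) < grad_tol)
      return(list(x = x, f = f, g = g, iterations = it - 1L,
                  converged = TRUE, trace = trace, restarts = restarts,
                  message = "converged"))
    slope <- sum(g * d)
    # first trial step: reuse the previous accepted step length
    alpha0 <- if (is.na(alpha_prev)) 1 / max(1, vnorm(g))
              else max(1e-10, min(alpha_prev * 2, 1e4))
    ls <- line_search_secant(fn, gr, x, f, g, d, alpha0 = alpha0)
    if (!ls$ok) {
      d <- -g
      ls <- line_search_backtrack(fn, gr, x, f, g, d,
                                  alpha0 = 1 / max(1, vnorm(g)))
      if (!ls$ok)
        return(list(x = x, f = f, g = g, iterations = it,
                    converged = avg_atom_gradient(g) < grad_tol,
                    trace = trace, restarts = restarts,
                    message = "line search failed after maximum backtracks"))
    }
    g_new <- ls$g
    y <- g_new - g
    # Powell restart test: loss of conjugacy
    restart <- abs(sum(g_new * g)) >= 0.2 * sum(g_new * g_new)
    if (restart) {
      restarts <- restarts + 1L
      dt <- d; yt <- y
      d_new <- -g_new
    } else {
      dy <- sum(d * y)
      beta <- if (abs(dy) > 1e-300) sum(g_new * y) / dy else 0
      d_new <- -g_new + beta * d
      if (!is.null(dt)) {
        dtyt <- sum(dt * yt)
        gamma <- if (abs(dtyt) > 1e-300) sum(g_new * yt) / dtyt else 0
        d_new <- d_new + gamma * dt
      }
      if (!all(is.finite(d_new)) ||
          sum(d_new * g_new) >= 0) {     # not a descent direction: restart
        restarts <- restarts + 1L
        dt <- d; yt <- y
        d_new <- -g_new
      }
    }
    x <- ls$x; f <- ls$f; g <- g_new; d <- d_new
    slope_prev <- slope
    alpha_prev <- ls$alpha
    trace <- c(trace, f)
  }
  list(x = x, f = f, g = g, iterations = max_iter,
       converged = avg_atom_gradient(g) < grad_tol, trace = trace,
       restarts = restarts, message = "maximum iterations reached")
}

#' Minimiser options
#'
#' @param method `"lbfgs"`, `"cg_powell_beale"`, or `"auto"` (lbfgs above
#'   400 atoms, CG below).
#' @param grad_tol Convergence threshold: mean per-atom gradient norm,
#'   (kcal/mol)/A.
#' @param max_iter Iteration cap.
#' @param m L-BFGS history length.
#' @param frozen Integer vector of frozen atom indices.
#' @return List of class `min_options`.
#' @export
minimizer_options <- function(method = c("auto", "lbfgs", "cg_powell_beale"),
                              grad_tol = 0.5, max_iter = 2000L, m = 10L,
                              frozen = integer(0)) {
  method <- match.arg(method)
  stopifnot(grad_tol > 0, m >= 1L)
  structure(list(method = method, grad_tol = grad_tol,
                 max_iter = as.integer(max_iter), m = as.integer(m),
                 frozen = as.integer(frozen)),
            class = "min_options")
}

#' Minimise the force-field energy of a system
#'
#' Frozen atoms keep their input coordinates bit-identically; convergence is
#' declared when the mean gradient norm over free atoms drops below
#' `grad_tol`.
#'
#' @param sys A `molsys` object.
#' @param topo A [perceive_topology()] result.
#' @param params A [parameter_set()].
#' @param settings A [nonbonded_settings()].
#' @param options A [minimizer_options()].
#' @return List of class `min_result`: `system` (optimised), `energy`,
#'   `avg_grad`, `iterations`, `converged`, `trace`, `message`.
#' @export
minimize <- function(sys, topo, params, settings = nonbonded_settings(),
                     options = minimizer_options()) {
  n <- nrow(sys$atoms)
  free <- setdiff(seq_len(n), options$frozen)
  if (length(free) == 0L) stop("empty free set: every atom is frozen")
  xyz0 <- coords(sys)
  pack <- function(m) as.vector(t(m[free, , drop = FALSE]))
  unpack <- function(x) {
    m <- xyz0
    m[free, ] <- matrix(x, ncol = 3L, byrow = TRUE)
    m
  }
  sys_w <- sys
  fn <- function(x) {
    coords(sys_w) <- unpack(x)
    energy_and_gradient(sys_w, topo, params, settings)$energy$total
  }
  gr <- function(x) {
    coords(sys_w) <- unpack(x)
    g <- energy_and_gradient(sys_w, topo, params, settings)$gradient
    as.vector(t(g[free, , drop = FALSE]))
  }
  method <- options$method
  if (method == "auto") method <- if (n > 400L) "lbfgs" else "cg_powell_beale"
  res <- if (method == "lbfgs")
    opt_lbfgs(fn, gr, pack(xyz0), options$grad_tol, options$max_iter,
              options$m)
  else
    opt_cg_powell_beale(fn, gr, pack(xyz0), options$grad_tol,
                        options$max_iter)
  coords(sys) <- unpack(res$x)
  structure(list(system = sys, energy = res$f,
                 avg_grad = avg_atom_gradient(res$g),
                 iterations = res$iterations, converged = res$converged,
                 trace = res$trace, message = res$message,
                 method = method),
            class = "min_result")
}

#' @export
print.min_result <- function(x, ...) {
  cat(sprintf("<min_result> %s: E = %.6f kcal/mol, avg |g| = %.4g, %d iter, %s\n",
              x$method, x$energy, x$avg_grad, x$iterations,
              if (x$converged) "converged" else x$message))
  invisible(x)
}

#' Partial optimisation of a protein-ligand complex
#'
#' All protein atoms outside `flexible_residues` are frozen; the ligand
#' selection is always free.  Equivalent to [minimize()] with the induced
#' frozen set.
#'
#' @param sys A `molsys` object.
#' @param topo,params,settings As in [minimize()].
#' @param ligand Atom indices of the ligand (always flexible).
#' @param flexible_residues Residue indices allowed to move (default none:
#'   rigid receptor, fully flexible ligand).
#' @param options A [minimizer_options()]; its `frozen` field is replaced.
#' @return A `min_result`.
#' @export
minimize_complex <- function(sys, topo, params,
                             settings = nonbonded_settings(),
                             ligand, flexible_residues = integer(0),
                             options = minimizer_options()) {
  n <- nrow(sys$atoms)
  flex_res_atoms <- which(sys$atoms$residue_index %in% flexible_residues)
  free <- union(ligand, flex_res_atoms)
  frozen <- setdiff(seq_len(n), free)
  if (length(free) == 0L) stop("empty free set")
  options$frozen <- frozen
  minimize(sys, topo, params, settings, options)
}

#' Heavy-atom RMSD without superposition
#'
#' Plain root-mean-square deviation over non-hydrogen atoms between two
#' conformations of the same system (the rigid-receptor validation
#' convention: no refitting).
#'
#' @param reference,optimised `molsys` objects with identical atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd_heavy <- function(reference, optimised) {
  if (nrow(reference$atoms) != nrow(optimised$atoms))
    stop("atom-count mismatch")
  heavy <- reference$atoms$element != "H"
  d <- coords(reference)[heavy, , drop = FALSE] -
    coords(optimised)[heavy, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}
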