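# Velocity-Verlet molecular dynamics with Berendsen weak-coupling
# temperature control.
#
# Units: positions A, time fs, velocities A/fs, masses amu, energies
# kcal/mol.  The single conversion constant
#   1 kcal/mol / (A amu) = 4.184e-4 A/fs^2
# maps forces to accelerations; kB = 0.0019872041 kcal/(mol K).
# Degrees of freedom: 3N - 3 (centre-of-mass momentum removed).

KB_KCAL <- 0.0019872041
ACC_CONV <- 4.184e-4

#' Molecular dynamics options
#'
#' @param dt Time step in fs.
#' @param n_steps Number of steps.
#' @param T0 Target temperature in K.
#' @param tau Berendsen coupling time in fs (must be >= dt when the
#'   thermostat is on).
#' @param thermostat `"on"` or `"off"`.
#' @param seed Integer seed for the velocity draw.
#' @param report_interval Snapshot interval in steps.
#' @return List of class `md_options`.
#' @export
md_options <- function(dt = 1.0, n_steps = 1000L, T0 = 300, tau = 100,
                       thermostat = c("on", "off"), seed = 1L,
                       report_interval = 10L) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0)
  if (thermostat == "on" && tau < dt)
    stop("tau must be >= dt when the thermostat is on")
  structure(list(dt = dt, n_steps = as.integer(n_steps), T0 = T0, tau = tau,
                 thermostat = thermostat, seed = as.integer(seed),
                 report_interval = as.integer(report_interval)),
            class = "md_options")
}

kinetic_energy <- function(vel, mass) {
  0.5 * sum(mass * rowSums(vel * vel)) / ACC_CONV
}

instantaneous_temperature <- function(vel, mass, ndof = NULL) {
  if (is.null(ndof)) ndof <- max(1L, 3L * nrow(vel) - 3L)
  2 * kinetic_energy(vel, mass) / (ndof * KB_KCAL)
}

#' Draw Maxwell-Boltzmann initial velocities
#'
#' Gaussian per-component draw at `T0`, centre-of-mass momentum removed,
#' then rescaled so the sample temperature equals `T0` exactly (for N > 1).
#' Deterministic under a fixed seed.
#'
#' @param sys A `molsys` object (masses from elements).
#' @param T0 Temperature in K (>= 0).
#' @param seed Integer seed.
#' @return N x 3 matrix of velocities in A/fs.
#' @export
initialize_velocities <- function(sys, T0, seed = 1L) {
  if (T0 < 0) stop("temperature must be non-negative")
  n <- nrow(sys$atoms)
  mass <- element_mass(sys$atoms$element)
  if (T0 == 0) return(matrix(0, n, 3L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd_v <- sqrt(KB_KCAL * T0 * ACC_CONV / mass)
  vel <- matrix(stats::rnorm(3L * n), n, 3L) * sd_v
  # remove centre-of-mass momentum
  p <- colSums(vel * mass)
  vel <- sweep(vel, 2L, p / sum(mass))
  if (n > 1L) {
    Tcur <- instantaneous_temperature(vel, mass)
    if (Tcur > 0) vel <- vel * sqrt(T0 / Tcur)
  }
  vel
}

#' One velocity-Verlet step
#'
#' Advances positions and velocities by `dt`; with the thermostat on,
#' velocities are scaled afterwards by
#' `lambda = sqrt(1 + (dt/tau) (T0/T - 1))` (Berendsen weak coupling).
#'
#' @param state List with `positions`, `velocities` (N x 3 matrices).
#' @param force_fn Function(positions) -> list(energy, forces N x 3
#'   kcal/mol/A).
#' @param forces Current forces (from the previous step's evaluation).
#' @param mass Numeric vector of masses (amu).
#' @param options An [md_options()].
#' @return List: `positions`, `velocities`, `forces`, `potential`,
#'   `kinetic`, `temperature`, `lambda`.
#' @export
md_step <- function(state, force_fn, forces, mass, options) {
  dt <- options$dt
  acc <- forces * ACC_CONV / mass
  vhalf <- state$velocities + 0.5 * dt * acc
  pos <- state$positions + dt * vhalf
  if (any(!is.finite(pos)))
    stop("MD blow-up: non-finite coordinates")
  fe <- force_fn(pos)
  acc2 <- fe$forces * ACC_CONV / mass
  vel <- vhalf + 0.5 * dt * acc2
  lambda <- 1
  Tinst <- instantaneous_temperature(vel, mass)
  if (options$thermostat == "on" && Tinst > 0) {
    lambda <- berendsen_lambda(Tinst, options$T0, dt, options$tau)
    vel <- vel * lambda
    Tinst <- instantaneous_temperature(vel, mass)
  }
  list(positions = pos, velocities = vel, forces = fe$forces,
       potential = fe$energy, kinetic = kinetic_energy(vel, mass),
       temperature = Tinst, lambda = lambda)
}

#' Berendsen velocity scaling factor
#'
#' `lambda = sqrt(1 + (dt/tau) (T0/T - 1))`.
#'
#' @param T Instantaneous temperature (K), positive.
#' @param T0 Target temperature (K).
#' @param dt,tau Time step and coupling time (same units).
#' @return The scaling factor.
#' @export
berendsen_lambda <- function(T, T0, dt, tau) {
  sqrt(1 + (dt / tau) * (T0 / T - 1))
}

#' Run molecular dynamics
#'
#' @param sys A `molsys` object (chemically complete: hydrogens present
#'   where the force field expects them).
#' @param topo,params,settings Force-field inputs as in
#'   [energy_and_gradient()].
#' @param options An [md_options()].
#' @param velocities Optional N x 3 start velocities; default drawn by
#'   [initialize_velocities()].
#' @return List of class `trajectory`: `frames` (list of snapshots with
#'   `step`, `positions`, `velocities`, `potential`, `kinetic`, `total`,
#'   `temperature`), `log` (data.frame per report step), `final` (the final
#'   state), `system`.
#' @export
run_md <- function(sys, topo, params, settings = nonbonded_settings(),
                   options = md_options(), velocities = NULL) {
  mass <- element_mass(sys$atoms$element)
  sys_w <- sys
  force_fn <- function(pos) {
    coords(sys_w) <- pos
    eg <- energy_and_gradient(sys_w, topo, params, settings)
    list(energy = eg$energy$total, forces = -eg$gradient)
  }
  if (is.null(velocities))
    velocities <- initialize_velocities(sys, options$T0, options$seed)
  state <- list(positions = coords(sys), velocities = velocities)
  fe <- force_fn(state$positions)
  forces <- fe$forces
  pot <- fe$energy
  kin <- kinetic_energy(velocities, mass)
  frames <- list()
  log <- vector("list", options$n_steps %/% options$report_interval + 1L)
  nlog <- 0L
  snap <- function(step, st, pot, kin) {
    list(step = step, positions = st$positions,
         velocities = st$velocities, potential = pot, kinetic = kin,
         total = pot + kin,
         temperature = instantaneous_temperature(st$velocities, mass))
  }
  frames[[1L]] <- snap(0L, state, pot, kin)
  for (step in seq_len(options$n_steps)) {
    st <- tryCatch(md_step(state, force_fn, forces, mass, options),
                   error = function(e)
                     stop("MD failure at step ", step, ": ",
                          conditionMessage(e)))
    state <- list(positions = st$positions, velocities = st$velocities)
    forces <- st$forces
    if (step %% options$report_interval == 0L || step == options$n_steps) {
      frames[[length(frames) + 1L]] <- snap(step, state, st$potential,
                                            st$kinetic)
      nlog <- nlog + 1L
      log[[nlog]] <- data.frame(step = step, KE = st$kinetic,
                                PE = st$potential,
                                E = st$kinetic + st$potential,
                                T = st$temperature)
    }
  }
  coords(sys) <- state$positions
  structure(list(frames = frames, log = do.call(rbind, log[seq_len(nlog)]),
                 final = c(state, list(forces = forces)), system = sys),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  nf <- length(x$frames)
  last <- x$frames[[nf]]
  cat(sprintf("<trajectory> %d frames, final step %d: E = %.4f kcal/mol, T = %.1f K\n",
              nf, last$step, last$total, last$temperature))
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ text
#' @param traj A `trajectory`.
#' @param sys The `molsys` the trajectory belongs to.
#' @return Character scalar of concatenated XYZ frames.
#' @export
write_trajectory_xyz <- function(traj, sys) {
  paste0(vapply(traj$frames, function(fr) {
    coords(sys) <- fr$positions
    write_xyz(sys, comment = sprintf("step %d E %.6f", fr$step, fr$total))
  }, character(1L)), collapse = "")
}
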