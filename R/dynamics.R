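#' Langevin thermostat noise draws
#'
#' Per-particle Gaussian noise vectors for one step of the Langevin
#' integrator.  Each component is an independent Gaussian with mean zero and
#' variance \eqn{2\gamma k_B T / (m_i \Delta t)} (in engine acceleration
#' units, i.e. including the kcal/mol-to-A/fs^2 conversion).  The stream is
#' counter-based — keyed by (seed, step, particle slot) — so draws are
#' independent across particles and steps and identical regardless of
#' evaluation order or worker count.
#'
#' @param masses Particle masses, amu.
#' @param temperature K.
#' @param gamma Friction, 1/fs.  Zero yields all-zero noise.
#' @param dt Time step, fs.
#' @param seed Integer seed.
#' @param step Step index the draws belong to.
#' @return N x 3 matrix of noise accelerations, A/fs^2.
#' @export
langevin_noise <- function(masses, temperature, gamma, dt, seed, step = 0) {
  n <- length(masses)
  if (gamma == 0) return(matrix(0, n, 3))
  sd <- sqrt(2 * gamma * .kB * temperature * .ACC / (masses * dt))
  z <- cpp_gauss_stream(seed, step, 0, 3L * n)
  matrix(z, n, 3, byrow = TRUE) * sd
}

#' Maxwell-Boltzmann initial velocities
#'
#' @param masses amu.
#' @param temperature K.
#' @param seed Integer seed (draws use the counter-based stream at a
#'   reserved step index so they never collide with thermostat noise).
#' @return N x 3 velocity matrix, A/fs.
#' @export
maxwell_velocities <- function(masses, temperature, seed) {
  n <- length(masses)
  sd <- sqrt(.kB * temperature * .ACC / masses)
  z <- cpp_gauss_stream(seed, 2^40, 0, 3L * n)
  matrix(z, n, 3, byrow = TRUE) * sd
}

#' Run Langevin (or NVE) dynamics
#'
#' Velocity-Verlet integration with the Langevin thermostat: the total force
#' is the potential gradient plus \eqn{-m\gamma v} friction and the
#' counter-based Gaussian noise of [langevin_noise()].  With `gamma = 0` the
#' scheme reduces to plain energy-conserving velocity Verlet.  Neighbor
#' lists are rebuilt every `nb_interval` steps (default 20).
#'
#' Identical seeds and settings give bit-identical trajectories.
#'
#' @param system A [cg_system()].
#' @param frame Initial [cg_frame()]; if it has no velocities a
#'   Maxwell-Boltzmann draw at `temperature` is used (NVE runs start at
#'   rest unless velocities are supplied).
#' @param nsteps Number of steps.
#' @param dt Time step, fs (default 10).
#' @param temperature K (default: the system's).
#' @param gamma Friction, 1/fs.  Default 0.001 (= 1/ps).  This is a free
#'   parameter of the thermostat, not a property of the models; see the
#'   package vignette.
#' @param seed Integer seed for the noise stream.
#' @param nb_interval Neighbor-list update interval, steps.
#' @param out_stride Save a frame every this many steps (0 = none).
#' @param log_stride Log energies every this many steps (0 = none).
#' @param step_offset Absolute step index of the first step (for chunked
#'   continuation runs; the noise stream is keyed by absolute step).
#' @return Object of class `cg_trajectory`: list with `final` (a
#'   [cg_frame()]), `frames` (list of position matrices), `energies`
#'   (data.frame: step, kinetic, potential and per-term energies).
#' @export
cg_run <- function(system, frame, nsteps, dt = 10, temperature = NULL,
                   gamma = 0.001, seed = 1, nb_interval = 20L,
                   out_stride = 0L, log_stride = 0L, step_offset = 0) {
  stopifnot(inherits(system, "cg_system"), inherits(frame, "cg_frame"))
  if (is.null(temperature)) temperature <- system$temperature
  n <- system$engine$n
  stopifnot(nrow(frame$positions) == n)
  periodic <- !is.null(frame$box)
  if (periodic) .check_box_rule(system, frame$box)
  vel <- frame$velocities
  if (is.null(vel)) {
    vel <- if (gamma > 0) {
      maxwell_velocities(system$engine$mass, temperature, seed)
    } else {
      matrix(0, n, 3)
    }
  }
  out <- cpp_run(system$engine, frame$positions, vel,
                 if (periodic) frame$box else c(0, 0, 0), periodic,
                 as.integer(nsteps), dt, temperature, gamma,
                 seed, step_offset, as.integer(nb_interval),
                 as.integer(out_stride), as.integer(log_stride))
  frames <- list()
  if (out$n_frames > 0) {
    for (k in seq_len(out$n_frames)) {
      frames[[k]] <- out$trajectory[((k - 1) * n + 1):(k * n), , drop = FALSE]
    }
  }
  energies <- NULL
  if (out$n_log > 0) {
    energies <- as.data.frame(out$energy_log[seq_len(out$n_log), ,
                                             drop = FALSE])
    names(energies) <- c("step", "kinetic", "potential", "bond", "angle",
                         "dihedral", "gauss13", "contact_go", "exv", "ele",
                         "hps", "base_stack", "base_pair", "cross_stack",
                         "pwmcos", "hb")
  }
  final <- cg_frame(out$positions, out$velocities, box = frame$box,
                    step = frame$step + nsteps,
                    time = frame$time + nsteps * dt)
  structure(list(final = final, frames = frames, energies = energies,
                 abs_step = out$abs_step, dt = dt, out_stride = out_stride),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("CG trajectory:", length(x$frames), "saved frames, final step",
      x$final$step, "\n")
  if (!is.null(x$energies)) {
    tail1 <- x$energies[nrow(x$energies), ]
    cat(sprintf("  final KE %.3f, PE %.3f kcal/mol\n",
                tail1$kinetic, tail1$potential))
  }
  invisible(x)
}
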