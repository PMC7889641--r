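#' Langevin (BAOAB) dynamics at constant volume
#'
#' Integrates the coarse-grained model with a BAOAB-discretized Langevin
#' thermostat.  Per-bead masses come from the residue parameter table;
#' the friction is gamma = 1/`friction_time_ps`.  The run is exactly
#' reproducible for a fixed seed (single-threaded integration; the
#' thermostat noise stream is seeded independently of R's RNG).
#'
#' @param state A `system_state` (from [init_slab()] or a previous run).
#' @param scaling An `interaction_scaling`.
#' @param temperature Target temperature, K.
#' @param dt_fs Time step, fs (default 10).
#' @param friction_time_ps Thermostat relaxation time, ps (default 5).
#' @param n_steps Number of integration steps.
#' @param thin Store a frame (and an energy-log row) every `thin` steps.
#' @param rng_seed Integer seed (thermostat noise and, when
#'   `init_velocities`, the Maxwell-Boltzmann draw).
#' @param init_velocities Draw initial velocities from the
#'   Maxwell-Boltzmann distribution at `temperature` (default TRUE when
#'   the state's velocities are all zero).
#' @param restraints Optional harmonic position restraints (see
#'   [system_energy_forces()]).
#' @param com_every Re-zero net momentum every this many steps.
#' @return A `slab_trajectory`: `frames` (3 x N x F array, nm),
#'   `frame_time_ps`, `energy_log` (data frame `step`, `time_ps`,
#'   `E_pot`, `E_kin`, `T_inst`), `final_state`, plus metadata
#'   (`temperature`, `scaling`, `seed`, `dt_fs`, `box`, `beads`).
#' @export
langevin_run <- function(state, scaling, temperature, dt_fs = 10,
                         friction_time_ps = 5, n_steps = 10000,
                         thin = 100, rng_seed = 1,
                         init_velocities = all(state$velocities == 0),
                         restraints = NULL, com_every = 1000) {
  stopifnot(inherits(state, "system_state"),
            inherits(scaling, "interaction_scaling"))
  dt_ps <- dt_fs / 1000
  # stability: dt at most a tenth of the stiffest oscillation period
  ks <- state$bonds$k
  if (!is.null(restraints)) ks <- c(ks, restraints$k)
  if (length(ks) > 0 && max(ks) > 0) {
    omega_max <- sqrt(max(ks) / min(state$beads$mass))
    if (dt_ps > 0.1 * 2 * pi / omega_max) {
      stop("dt = ", dt_fs, " fs unstable for stiffest spring (limit ",
           signif(0.1 * 2 * pi / omega_max * 1000, 3), " fs)")
    }
  }
  vel <- state$velocities
  if (init_velocities) {
    set.seed(rng_seed)
    n <- nrow(state$positions)
    sdv <- sqrt(.kB * temperature / state$beads$mass)
    vel <- matrix(rnorm(3 * n), n, 3) * sdv
  }
  res <- cg_langevin(state$positions, vel, state$box,
                     .bead_arrays(state$beads, scaling),
                     as.list(state$bonds), .scal_list(scaling),
                     temperature, dt_ps, friction_time_ps,
                     as.integer(n_steps), as.integer(thin),
                     as.integer(rng_seed), restraints,
                     com_every = as.integer(com_every))
  nf <- res$n_frames
  frames <- res$frames
  dim(frames) <- c(3, nrow(state$positions), nf)
  elog <- as.data.frame(res$energy_log)
  names(elog) <- c("step", "time_ps", "E_pot", "E_kin", "T_inst")
  final_state <- state
  final_state$positions <- res$positions
  final_state$velocities <- res$velocities
  final_state$time_ps <- state$time_ps + n_steps * dt_ps
  structure(list(frames = frames, frame_time_ps = res$frame_time_ps,
                 energy_log = elog, final_state = final_state,
                 box = state$box, beads = state$beads,
                 temperature = temperature, scaling = scaling,
                 seed = rng_seed, dt_fs = dt_fs, thin = thin),
            class = "slab_trajectory")
}

#' @export
print.slab_trajectory <- function(x, ...) {
  cat("slab_trajectory: ", dim(x$frames)[2], " beads, ", dim(x$frames)[3],
      " frames, T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj A `slab_trajectory`.
#' @param f Frame index.
#' @export
get_frame <- function(traj, f) t(traj$frames[, , f])

#' Berendsen NPT pre-equilibration
#'
#' Weak-coupling isotropic volume rescaling toward a target pressure;
#' an optional stage before slab elongation (the slab may instead be
#' built directly by [init_slab()]).
#'
#' @inheritParams langevin_run
#' @param pressure_bar Target pressure, bar (default 1).
#' @param tau_p_ps Pressure coupling time, ps; `Inf` disables coupling.
#' @param beta_T Isothermal compressibility used by the weak coupling,
#'   1/bar.
#' @return The relaxed `system_state` (positions, velocities and box).
#' @export
npt_equilibrate <- function(state, scaling, temperature, pressure_bar = 1,
                            tau_p_ps = 1, n_steps = 10000, dt_fs = 10,
                            friction_time_ps = 5, rng_seed = 1,
                            beta_T = 0.01,
                            init_velocities = all(state$velocities == 0)) {
  stopifnot(inherits(state, "system_state"))
  dt_ps <- dt_fs / 1000
  vel <- state$velocities
  if (init_velocities) {
    set.seed(rng_seed)
    n <- nrow(state$positions)
    sdv <- sqrt(.kB * temperature / state$beads$mass)
    vel <- matrix(rnorm(3 * n), n, 3) * sdv
  }
  bar_to_internal <- 0.0602214076  # kJ/mol/nm^3 per bar
  res <- cg_berendsen(state$positions, vel, state$box,
                      .bead_arrays(state$beads, scaling),
                      as.list(state$bonds), .scal_list(scaling),
                      temperature, dt_ps, friction_time_ps,
                      pressure_bar * bar_to_internal, tau_p_ps,
                      beta_T / bar_to_internal,
                      as.integer(n_steps), as.integer(rng_seed))
  out <- state
  out$positions <- res$positions
  out$velocities <- res$velocities
  out$box <- as.numeric(res$box)
  out$time_ps <- state$time_ps + n_steps * dt_ps
  out
}

#' Direct-coexistence production over a temperature ladder
#'
#' For each temperature: build a fresh slab (seeded deterministically
#' from `rng_seed` and the ladder index), then run NVT Langevin
#' production.  Downstream analyses discard a configurable equilibration
#' fraction of each trajectory.
#'
#' @inheritParams init_slab
#' @param scaling An `interaction_scaling`, or a function(T) returning
#'   one per temperature.
#' @param temperatures Temperature ladder, K (>= 1 entry).
#' @param n_steps,dt_fs,friction_time_ps,thin Passed to [langevin_run()].
#' @param rng_seed Base seed; temperature k uses `rng_seed + 7919 * k`.
#' @return Named list (by temperature) of `slab_trajectory` objects.
#' @export
run_direct_coexistence <- function(topologies, counts, box, params,
                                   scaling, temperatures,
                                   n_steps = 100000, dt_fs = 10,
                                   friction_time_ps = 5, thin = 1000,
                                   slab_fraction = 0.25, rng_seed = 1) {
  stopifnot(length(temperatures) >= 1)
  out <- vector("list", length(temperatures))
  names(out) <- as.character(temperatures)
  for (k in seq_along(temperatures)) {
    Tk <- temperatures[k]
    scal_k <- if (is.function(scaling)) scaling(Tk) else scaling
    seed_k <- rng_seed + 7919L * k
    st <- init_slab(topologies, counts, box, params,
                    slab_fraction = slab_fraction, rng_seed = seed_k)
    out[[k]] <- langevin_run(st, scal_k, Tk, dt_fs = dt_fs,
                             friction_time_ps = friction_time_ps,
                             n_steps = n_steps, thin = thin,
                             rng_seed = seed_k)
  }
  out
}

#' Write a trajectory as extended-XYZ text
#'
#' One block per frame; the comment line carries the box and time.
#'
#' @param traj A `slab_trajectory`.
#' @param path Output file.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$frames)[2]
  for (f in seq_len(dim(traj$frames)[3])) {
    xyz <- get_frame(traj, f)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" time_ps=%g',
      traj$box[1], traj$box[2], traj$box[3], traj$frame_time_ps[f]), con)
    writeLines(sprintf("%s %.5f %.5f %.5f", traj$beads$code,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Write the per-frame energy log as CSV
#' @param traj A `slab_trajectory`.
#' @param path Output file.
#' @export
write_energy_log <- function(traj, path) {
  utils::write.table(traj$energy_log, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-frame energy breakdown of a trajectory
#'
#' Re-evaluates the potential on every stored frame and decomposes it
#' into bonded, hydrophobic, electrostatic and cation-pi contributions;
#' optionally written as CSV with columns
#' `frame,hydrophobic,electrostatic,cation_pi,bonded,total`.
#'
#' @param traj A `slab_trajectory`.
#' @param scaling Interaction scaling to evaluate under (defaults to the
#'   trajectory's own).
#' @param path Optional CSV output path.
#' @return Data frame of per-frame energy components (kJ/mol).
#' @export
energy_breakdown <- function(traj, scaling = traj$scaling, path = NULL) {
  stopifnot(inherits(traj, "slab_trajectory"))
  st <- traj$final_state
  rows <- lapply(seq_len(dim(traj$frames)[3]), function(f) {
    st$positions <- get_frame(traj, f)
    ef <- system_energy_forces(st, scaling)
    data.frame(frame = f, hydrophobic = ef$hydrophobic,
               electrostatic = ef$electrostatic,
               cation_pi = ef$cation_pi, bonded = ef$bonded,
               total = ef$bonded + ef$hydrophobic + ef$electrostatic +
                 ef$cation_pi)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
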