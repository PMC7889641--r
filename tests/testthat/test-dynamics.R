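test_that("slab construction places all beads in the central slab", {
  topo <- build_topology(pr25_seq(), name = "PR25")
  st <- init_slab(topo, 20, c(5, 5, 20), hps, slab_fraction = 0.25,
                  rng_seed = 1, minimize_steps = 0)
  expect_equal(nrow(st$positions), 500)
  z <- st$positions[, 3]
  expect_true(all(z >= 20 * 0.375 - 0.38 & z <= 20 * 0.625 + 0.38))
  # no inter-bead overlap below 0.7 * min sigma (non-bonded)
  d <- as.matrix(dist(st$positions))
  diag(d) <- Inf
  bonded <- cbind(st$bonds$i + 1, st$bonds$j + 1)
  d[bonded] <- Inf
  d[bonded[, 2:1]] <- Inf
  expect_gte(min(d), 0.7 * min(hps$sigma) - 1e-9)
})

test_that("slab construction is bit-identical under a fixed seed", {
  topo <- build_topology(fus_like_seq(2))
  a <- init_slab(topo, 5, c(5, 5, 20), hps, rng_seed = 42)
  b <- init_slab(topo, 5, c(5, 5, 20), hps, rng_seed = 42)
  expect_identical(a$positions, b$positions)
  c <- init_slab(topo, 5, c(5, 5, 20), hps, rng_seed = 43)
  expect_false(identical(c$positions, a$positions))
})

test_that("impossible density requests fail with a helpful error", {
  topo <- build_topology(strrep("W", 30))
  expect_error(
    init_slab(topo, 60, c(2, 2, 8), hps, slab_fraction = 0.1,
              max_retries = 5),
    "retry budget")
})

test_that("time step stability guard refuses too-large dt", {
  topo <- build_topology("GG")
  st <- init_slab(topo, 2, c(4, 4, 4), hps, slab_fraction = 0.9)
  expect_error(
    langevin_run(st, interaction_scaling(), 300, dt_fs = 200, n_steps = 10),
    "unstable")
})

test_that("Langevin trajectories are reproducible under a fixed seed", {
  topo <- build_topology(fus_like_seq(1))
  st <- init_slab(topo, 4, c(4, 4, 12), hps, rng_seed = 2)
  scal <- apply_regime("moderate", "fus_like")
  t1 <- langevin_run(st, scal, 280, n_steps = 400, thin = 100, rng_seed = 7)
  t2 <- langevin_run(st, scal, 280, n_steps = 400, thin = 100, rng_seed = 7)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energy_log, t2$energy_log)
  t3 <- langevin_run(st, scal, 280, n_steps = 400, thin = 100, rng_seed = 8)
  expect_false(identical(t3$frames, t1$frames))
})

test_that("zero-temperature dynamics dissipate energy monotonically", {
  # at T = 0 the thermostat is pure friction: total energy can only
  # fall (inertia lets the potential alone rise transiently), and the
  # run ends in a lower potential-energy state
  topo <- build_topology(fus_like_seq(1))
  st <- init_slab(topo, 3, c(4, 4, 8), hps, rng_seed = 3)
  scal <- apply_regime("high", "fus_like")
  tr <- langevin_run(st, scal, temperature = 0, n_steps = 2000,
                     thin = 100, rng_seed = 1, init_velocities = FALSE)
  e_tot <- tr$energy_log$E_pot + tr$energy_log$E_kin
  expect_true(all(diff(e_tot) <= 1e-8))
  expect_lt(tail(tr$energy_log$E_pot, 1), tr$energy_log$E_pot[1])
})

test_that("single tethered bead satisfies equipartition <x^2> = kBT/k", {
  topo <- build_topology("G")
  sys <- condensr:::make_system(topo, 1, hps)
  st <- structure(list(positions = matrix(5, 1, 3),
                       velocities = matrix(0, 1, 3), box = c(10, 10, 10),
                       beads = sys$beads, bonds = sys$bonds, time_ps = 0),
                  class = "system_state")
  k_trap <- 100
  Tset <- 300
  res <- list(k = k_trap, center = matrix(5, 1, 3))
  tr <- langevin_run(st, interaction_scaling(), Tset, n_steps = 1e6,
                     thin = 100, rng_seed = 21, restraints = res,
                     com_every = 0)
  x <- tr$frames[1, 1, ] - 5
  y <- tr$frames[2, 1, ] - 5
  z <- tr$frames[3, 1, ] - 5
  msd <- c(mean(x^2), mean(y^2), mean(z^2))
  expected <- 8.31446e-3 * Tset / k_trap
  # standard error from block averaging over 20 blocks, all 3 axes
  blocks <- split(x^2, cut(seq_along(x), 20))
  se <- sd(vapply(blocks, mean, numeric(1))) / sqrt(20)
  for (m in msd) expect_lt(abs(m - expected), 3 * se)
})

test_that("thermostat holds the kinetic temperature within 2%", {
  topo <- build_topology(fus_like_seq(3))
  st <- init_slab(topo, 6, c(4.5, 4.5, 18), hps, rng_seed = 4)
  scal <- apply_regime("moderate", "fus_like")
  tr <- langevin_run(st, scal, 280, n_steps = 15000, thin = 150,
                     rng_seed = 5)
  Tbar <- mean(tail(tr$energy_log$T_inst, 60))
  expect_lt(abs(Tbar - 280) / 280, 0.02)
  # net momentum is re-zeroed during the run
  p <- colSums(tr$final_state$velocities * tr$final_state$beads$mass)
  expect_lt(max(abs(p)) / sum(tr$final_state$beads$mass), 0.05)
})

test_that("Berendsen stage drives an ideal gas toward N kB T / P", {
  # 60 single-bead chains, all interactions off
  topo <- build_topology("G")
  st <- init_slab(topo, 60, c(8, 8, 8), hps, slab_fraction = 0.9,
                  rng_seed = 6, minimize_steps = 0)
  scal <- interaction_scaling(eps_ah = 0, chi = 0,
                              cutoff_hydro = 0.2, cutoff_elec_max = 0.2)
  out <- npt_equilibrate(st, scal, 300, pressure_bar = 1, tau_p_ps = 0.5,
                         n_steps = 30000, rng_seed = 7, beta_T = 0.02)
  v_target <- 60 * 8.31446e-3 * 300 / 0.0602214076 # nm^3
  expect_lt(abs(prod(out$box) - v_target) / v_target, 0.2)
  # infinite coupling time leaves the volume untouched
  out2 <- npt_equilibrate(st, scal, 300, tau_p_ps = Inf, n_steps = 500,
                          rng_seed = 7)
  expect_identical(out2$box, st$box)
  # determinism
  out3 <- npt_equilibrate(st, scal, 300, pressure_bar = 1, tau_p_ps = 0.5,
                          n_steps = 1000, rng_seed = 7, beta_T = 0.02)
  out4 <- npt_equilibrate(st, scal, 300, pressure_bar = 1, tau_p_ps = 0.5,
                          n_steps = 1000, rng_seed = 7, beta_T = 0.02)
  expect_identical(out3$positions, out4$positions)
  expect_identical(out3$box, out4$box)
})

test_that("coexistence ladders return one trajectory per temperature", {
  topo <- build_topology(fus_like_seq(1))
  runs <- run_direct_coexistence(topo, 3, c(4, 4, 12), hps,
                                 scaling = apply_regime("high", "fus_like"),
                                 temperatures = c(250, 300),
                                 n_steps = 300, thin = 100, rng_seed = 1)
  expect_named(runs, c("250", "300"))
  expect_s3_class(runs[["250"]], "slab_trajectory")
  expect_equal(dim(runs[["300"]]$frames)[3], 3)
})

test_that("ideal chains disperse from the initial slab", {
  topo <- build_topology(strrep("G", 10))
  st <- init_slab(topo, 6, c(4, 4, 16), hps, slab_fraction = 0.25,
                  rng_seed = 8)
  # cohesion off: purely repulsive cores, no electrostatics
  scal <- interaction_scaling(chi = 0, hydro_scale = 1e-6)
  tr <- langevin_run(st, scal, 300, n_steps = 100000, thin = 1000,
                     rng_seed = 9)
  prof0 <- density_profile(tr, n_bins = 16, equil_fraction = 0)
  # occupancy of the outer half of the long axis grows from ~0
  z_last <- tr$frames[3, , dim(tr$frames)[3]]
  outer_frac <- mean(z_last < 4 | z_last > 12)
  expect_gt(outer_frac, 0.2)
  expect_equal(sum(prof0$density * attr(prof0, "bin_volume")) / 1.66053907,
               attr(prof0, "total_mass"), tolerance = 1e-9)
})

test_that("trajectory and energy-log writers emit the documented formats", {
  topo <- build_topology("GYG")
  st <- init_slab(topo, 2, c(4, 4, 8), hps, rng_seed = 10)
  tr <- langevin_run(st, interaction_scaling(), 300, n_steps = 200,
                     thin = 100, rng_seed = 1)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(tr, xyz)
  lines <- readLines(xyz)
  expect_equal(lines[1], "6")
  expect_match(lines[2], "Lattice=.*time_ps=")
  expect_equal(length(lines), 2 * (6 + 2))
  csv <- tempfile(fileext = ".csv")
  write_energy_log(tr, csv)
  elog <- read.csv(csv)
  expect_named(elog, c("step", "time_ps", "E_pot", "E_kin", "T_inst"))
  expect_equal(nrow(elog), 2)
  # per-frame breakdown columns sum exactly and round-trip as CSV
  bcsv <- tempfile(fileext = ".csv")
  bd <- energy_breakdown(tr, path = bcsv)
  expect_named(bd, c("frame", "hydrophobic", "electrostatic", "cation_pi",
                     "bonded", "total"))
  expect_equal(bd$total, bd$hydrophobic + bd$electrostatic +
                 bd$cation_pi + bd$bonded)
  expect_equal(nrow(read.csv(bcsv)), 2)
})
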