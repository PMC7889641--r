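test_that("Debye length matches the closed form and its limits", {
  # hand evaluation of sqrt(eps0*eps_r*kB*T/(2*NA*e^2*I)) with CODATA
  # constants, I = 0.15 mol/L, T = 298 K, eps_r = 80: 0.7927 nm
  expect_equal(debye_length(0.15, 298, 80), 0.7927, tolerance = 1e-3)
  expect_identical(debye_length(0, 298, 80), Inf)
  expect_error(debye_length(-0.1), ">= 0")
  # monotone decreasing in ionic strength
  I <- c(0.01, 0.05, 0.15, 0.5, 1.5, 3)
  expect_true(all(diff(debye_length(I, 298, 80)) < 0))
})

test_that("Ashbaugh-Hatch term has the prescribed minimum and shift", {
  s <- interaction_scaling(chi = 1, hydro_scale = 1)
  # lambda_ij = 1 (F-F): minimum is -eps up to the cutoff shift
  rmin <- 2^(1 / 6) * hps["F", "sigma"]
  e_ff <- pair_energy(rmin, "F", "F", hps, s)
  rc <- s$cutoff_hydro
  shift <- 4 * s$eps_ah * ((hps["F", "sigma"] / rc)^12 -
                             (hps["F", "sigma"] / rc)^6)
  expect_equal(e_ff$hydrophobic, -s$eps_ah - shift, tolerance = 1e-10)
  expect_equal(e_ff$hydrophobic, -0.8368, tolerance = 5e-3)
  # lambda_ij = 0 (R-R): the AH construction cancels the minimum
  rminR <- 2^(1 / 6) * hps["R", "sigma"]
  expect_equal(pair_energy(rminR, "R", "R", hps, s)$hydrophobic, 0,
               tolerance = 1e-12)
})

test_that("AH term is continuous at 2^(1/6) sigma for all lambda", {
  for (hs in c(0.3, 0.7, 1.0, 1.3)) {
    s <- interaction_scaling(hydro_scale = hs)
    for (pair in list(c("G", "F"), c("Y", "S"), c("R", "D"))) {
      sij <- mean(hps[pair, "sigma"])
      rmin <- 2^(1 / 6) * sij
      left <- pair_energy(rmin - 1e-9, pair[1], pair[2], hps, s)$hydrophobic
      right <- pair_energy(rmin + 1e-9, pair[1], pair[2], hps, s)$hydrophobic
      expect_lt(abs(left - right), 1e-6)
    }
  }
})

test_that("all pair terms vanish at their cutoffs and are symmetric", {
  s <- interaction_scaling(chi = 2, cation_pi_eps = 3)
  for (r in c(s$cutoff_hydro, s$cutoff_hydro + 0.5)) {
    e <- pair_energy(r, "Y", "R", hps, s)
    expect_equal(e$hydrophobic, 0)
    expect_equal(e$cation_pi, 0)
  }
  expect_equal(pair_energy(s$cutoff_elec, "R", "D", hps, s)$electrostatic, 0)
  for (r in c(0.5, 0.8, 1.5)) {
    a <- pair_energy(r, "R", "Y", hps, s)
    b <- pair_energy(r, "Y", "R", hps, s)
    expect_equal(a$total, b$total)
    expect_equal(a$cation_pi, b$cation_pi)
  }
})

test_that("electrostatics are exactly linear in chi and qi*qj", {
  s1 <- interaction_scaling(chi = 1)
  s2 <- interaction_scaling(chi = 2)
  r <- 0.7
  e1 <- pair_energy(r, "R", "R", hps, s1)$electrostatic
  e2 <- pair_energy(r, "R", "R", hps, s2)$electrostatic
  expect_equal(e2, 2 * e1)
  # opposite charges flip the sign exactly
  e_rd <- pair_energy(r, "R", "D", hps, s1)$electrostatic
  expect_equal(e_rd, -e1)
  # neutral pairs carry none
  expect_equal(pair_energy(r, "G", "S", hps, s1)$electrostatic, 0)
})

test_that("hydrophobic well depth is monotone in hydro_scale", {
  depths <- vapply(c(0.8, 1.0, 1.1, 1.3), function(hs) {
    s <- interaction_scaling(hydro_scale = hs)
    rmin <- 2^(1 / 6) * hps["Y", "sigma"]
    pair_energy(rmin, "Y", "Y", hps, s)$hydrophobic
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
})

test_that("buried residues scale their own lambda by 0.7 before averaging", {
  s <- interaction_scaling()
  rmin <- 2^(1 / 6) * hps["Y", "sigma"]
  free <- pair_energy(rmin, "Y", "Y", hps, s)$hydrophobic
  one_buried <- pair_energy(rmin, "Y", "Y", hps, s, buried_i = TRUE)$hydrophobic
  both_buried <- pair_energy(rmin, "Y", "Y", hps, s,
                             buried_i = TRUE, buried_j = TRUE)$hydrophobic
  lamY <- hps["Y", "lambda"]
  # depth at rmin is -lambda_ij * eps + core/shift bookkeeping; ratios of
  # (value - value_at_lambda0) recover the lambda_ij ratios exactly
  lam_ij <- c(lamY, (lamY + 0.7 * lamY) / 2, 0.7 * lamY)
  vals <- c(free, one_buried, both_buried)
  expect_equal(vals / vals[1], lam_ij / lam_ij[1], tolerance = 1e-6)
})

test_that("salt-regime presets carry the published scalings", {
  low <- apply_regime("low", "fus_like")
  expect_equal(low$chi, 4)
  expect_equal(low$hydro_scale, 1.0)
  expect_gt(low$cation_pi_eps, 0)
  mod <- apply_regime("moderate", "fus_like")
  expect_equal(mod$chi, 2)
  expect_equal(mod$hydro_scale, 1.0)
  expect_equal(mod$cation_pi_eps, 0)
  hi_f <- apply_regime("high", "fus_like")
  expect_equal(hi_f$chi, 1)
  expect_equal(hi_f$hydro_scale, 1.1)
  hi_p <- apply_regime("high", "pr_like")
  expect_equal(hi_p$chi, 1)
  expect_equal(hi_p$hydro_scale, 1.3)
  expect_error(apply_regime("medium"), "arg")
})

test_that("Arg-Arg repulsion is removed, not inverted, by the high-salt regime", {
  # with the HPS table's lambda_R = 0 the pair keeps no hydrophobic
  # attraction of its own; screening the chi = 4 Coulomb repulsion
  # brings the contact energy down to ~0
  rmin <- 2^(1 / 6) * hps["R", "sigma"]
  low <- pair_energy(rmin, "R", "R", hps,
                     interaction_scaling(chi = 4))$total
  high <- pair_energy(rmin, "R", "R", hps,
                      interaction_scaling(chi = 0, hydro_scale = 1.3))$total
  expect_gt(low, 1)          # strongly repulsive at low salt
  expect_lt(abs(high), 0.05) # neutralized at high salt
  expect_lt(high, low)
})

test_that("cation-pi well applies only to cation x aromatic pairs", {
  s <- interaction_scaling(cation_pi_eps = 3)
  r <- 2^(1 / 6) * mean(hps[c("R", "Y"), "sigma"])
  expect_lt(pair_energy(r, "R", "Y", hps, s)$cation_pi, -2.9)
  expect_equal(pair_energy(r, "R", "P", hps, s)$cation_pi, 0)
  expect_equal(pair_energy(r, "Y", "Y", hps, s)$cation_pi, 0)
  s0 <- interaction_scaling(cation_pi_eps = 0)
  expect_equal(pair_energy(r, "R", "Y", hps, s0)$cation_pi, 0)
})

test_that("breakdown total is the exact sum of its parts", {
  s <- interaction_scaling(chi = 2, cation_pi_eps = 3)
  for (r in c(0.45, 0.7, 1.2)) {
    e <- pair_energy(r, "K", "W", hps, s)
    expect_identical(e$total, e$hydrophobic + e$electrostatic + e$cation_pi)
  }
})

test_that("system energy/forces: bonded pair at rest length is force-free", {
  topo <- build_topology("GG", r0 = 0.38)
  st <- structure(list(
    positions = rbind(c(1, 1, 1), c(1.38, 1, 1)),
    velocities = matrix(0, 2, 3), box = c(4, 4, 4),
    beads = condensr:::make_system(topo, 1, hps)$beads,
    bonds = condensr:::make_system(topo, 1, hps)$bonds, time_ps = 0),
    class = "system_state")
  ef <- system_energy_forces(st, interaction_scaling())
  expect_equal(ef$bonded, 0, tolerance = 1e-12)
  expect_equal(ef$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(ef$forces)), 0, tolerance = 1e-10)
})

test_that("analytic forces match central finite differences to 1e-5", {
  topo1 <- build_topology(strrep("Y", 10))
  topo2 <- build_topology("RPDGYKSAQW")
  st <- init_slab(list(topo1, topo2), c(2, 1), c(4, 4, 4), hps,
                  slab_fraction = 0.9, rng_seed = 3)
  scal <- interaction_scaling(chi = 2, hydro_scale = 1.1, cation_pi_eps = 3)
  ef <- system_energy_forces(st, scal)
  h <- 1e-5
  set.seed(1)
  for (t in 1:12) {
    i <- sample(nrow(st$positions), 1)
    d <- sample(3, 1)
    stp <- st; stp$positions[i, d] <- stp$positions[i, d] + h
    stm <- st; stm$positions[i, d] <- stm$positions[i, d] - h
    fd <- -(system_energy_forces(stp, scal)$energy -
              system_energy_forces(stm, scal)$energy) / (2 * h)
    expect_lt(abs(ef$forces[i, d] - fd) / max(abs(fd), 1), 1e-5)
  }
})

test_that("energy decouples from chi when all charges are zero", {
  topo <- build_topology(strrep("G", 8))
  st <- init_slab(topo, 3, c(4, 4, 4), hps, slab_fraction = 0.9,
                  rng_seed = 5)
  e1 <- system_energy_forces(st, interaction_scaling(chi = 1))$energy
  e2 <- system_energy_forces(st, interaction_scaling(chi = 2))$energy
  expect_identical(e1, e2)
})

test_that("energy is invariant under translation and periodic image shifts", {
  topo <- build_topology("RPDGY")
  st <- init_slab(topo, 4, c(4, 4, 6), hps, slab_fraction = 0.8,
                  rng_seed = 11)
  scal <- interaction_scaling(chi = 2, cation_pi_eps = 3)
  e0 <- system_energy_forces(st, scal)$energy
  st_t <- st
  st_t$positions <- (st$positions +
                       matrix(c(1.3, 0.7, 2.1), nrow(st$positions), 3,
                              byrow = TRUE)) %% matrix(st$box,
                                                       nrow(st$positions),
                                                       3, byrow = TRUE)
  expect_equal(system_energy_forces(st_t, scal)$energy, e0,
               tolerance = 1e-9)
  st_i <- st
  st_i$positions[3, 1] <- st_i$positions[3, 1] + st$box[1] # image shift
  st_i$positions <- st_i$positions %% matrix(st$box, nrow(st$positions),
                                             3, byrow = TRUE)
  expect_equal(system_energy_forces(st_i, scal)$energy, e0,
               tolerance = 1e-9)
})

test_that("overlapping beads below the hard floor are refused by name", {
  topo <- build_topology("GG")
  sys <- condensr:::make_system(list(topo, topo), c(1, 1), hps)
  st <- structure(list(
    positions = rbind(c(1, 1, 1), c(1.38, 1, 1), c(1, 1, 1 + 1e-5),
                      c(1.38, 1, 1.5)),
    velocities = matrix(0, 4, 3), box = c(4, 4, 4),
    beads = sys$beads, bonds = sys$bonds, time_ps = 0),
    class = "system_state")
  expect_error(system_energy_forces(st, interaction_scaling()),
               "beads 1 and 3")
})
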