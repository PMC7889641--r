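test_that("single near-unbiased window reduces to the log-histogram", {
  # k_bias -> 0 degeneracy: PMF equals -kBT log(histogram) up to the
  # reference constant
  kT <- 8.31446e-3 * 298
  set.seed(3)
  # Boltzmann samples from U = 4 (x - 1)^2 (Gaussian, sd = sqrt(kT/8))
  x <- rnorm(40000, 1, sqrt(kT / 8))
  win <- umbrella_window(1, 1e-9, x, 298)
  pmf <- wham_solve(list(win), grid_spacing = 0.01, burn_in_fraction = 0,
                    reference_range = c(0.95, 1.05))
  h <- hist(x, breaks = c(pmf$r - 0.005, max(pmf$r) + 0.005),
            plot = FALSE)
  ref <- -kT * log(h$counts)
  ref[!is.finite(ref)] <- Inf
  sel <- is.finite(pmf$pmf) & is.finite(ref) & h$counts > 50
  diff <- pmf$pmf[sel] - ref[sel]
  expect_lt(diff(range(diff)), 0.35) # constant offset up to binning error
})

test_that("harmonic windows recover the true curvature within 5%", {
  wins <- harmonic_windows(k_true = 50, x0 = 0.8, n = 50000)
  pmf <- wham_solve(wins, burn_in_fraction = 0)
  sel <- is.finite(pmf$pmf) & pmf$r > 0.55 & pmf$r < 1.05
  fit <- lm(pmf ~ poly(r, 2, raw = TRUE), data = pmf[sel, ])
  curvature <- 2 * coef(fit)[[3]]
  expect_lt(abs(curvature - 50) / 50, 0.05)
  # fitted vertex recovers the minimum location
  vertex <- -coef(fit)[[2]] / curvature
  expect_lt(abs(vertex - 0.8), 0.02)
})

test_that("WHAM output is invariant to window order", {
  wins <- harmonic_windows(n = 5000)
  pmf1 <- wham_solve(wins, burn_in_fraction = 0)
  pmf2 <- wham_solve(rev(wins), grid = pmf1$r, burn_in_fraction = 0)
  expect_equal(pmf2$pmf, pmf1$pmf, tolerance = 1e-6)
})

test_that("burn-in removes the prescribed leading fraction of samples", {
  set.seed(1)
  good <- rnorm(9000, 0.8, 0.02)
  w_clean <- umbrella_window(0.8, 6000, good)
  # corrupt the first 10% with far-off equilibration transients
  w_dirty <- umbrella_window(0.8, 6000, c(rnorm(1000, 0.9, 0.001), good))
  p_clean <- wham_solve(list(w_clean), burn_in_fraction = 0,
                        reference_range = c(0.85, 0.9))
  p_dirty <- wham_solve(list(w_dirty), grid = p_clean$r,
                        burn_in_fraction = 0.1,
                        reference_range = c(0.85, 0.9))
  i1 <- which.min(p_clean$pmf)
  expect_equal(p_dirty$r[which.min(p_dirty$pmf)], p_clean$r[i1])
})

test_that("window files and manifests round-trip", {
  dir <- tempfile()
  dir.create(dir)
  set.seed(4)
  wins <- harmonic_windows(centers = c(0.6, 0.7), n = 200)
  files <- c("w1.csv", "w2.csv")
  for (i in 1:2) write_window(wins[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, "windows.txt")
  writeLines(c("# window list", files[1], "", files[2]), manifest)
  back <- read_window_manifest(manifest)
  expect_length(back, 2)
  expect_equal(back[[1]]$center, wins[[1]]$center)
  expect_equal(back[[2]]$samples, wins[[2]]$samples, tolerance = 1e-9)
  expect_equal(back[[1]]$k, wins[[1]]$k)
})

test_that("non-overlapping windows raise an island error", {
  set.seed(2)
  w1 <- umbrella_window(0.3, 6000, rnorm(1000, 0.3, 0.02))
  w2 <- umbrella_window(1.5, 6000, rnorm(1000, 1.5, 0.02))
  expect_error(wham_solve(list(w1, w2), burn_in_fraction = 0),
               "islands")
})

test_that("bootstrap band is seed-deterministic and shrinks for identical windows", {
  wins <- harmonic_windows(n = 4000)
  b1 <- bootstrap_pmf(wins, n_boot = 20, rng_seed = 5,
                      burn_in_fraction = 0)
  b2 <- bootstrap_pmf(wins, n_boot = 20, rng_seed = 5,
                      burn_in_fraction = 0)
  expect_identical(b1$err, b2$err)
  # replicate-identical windows: Dirichlet reweighting changes nothing
  w0 <- harmonic_windows(centers = 0.8, n = 5000)[[1]]
  same <- list(w0, w0, w0, w0)
  b3 <- bootstrap_pmf(same, n_boot = 15, rng_seed = 1,
                      burn_in_fraction = 0,
                      reference_range = c(0.85, 0.9))
  expect_lt(max(b3$err, na.rm = TRUE), 1e-8)
})

test_that("double-well PMF is recovered with coverage by the bootstrap band", {
  # quartic double well with minima at 0.45 and 0.95 nm, ~8 kJ/mol barrier
  kT <- 8.31446e-3 * 298
  U <- function(x) 2000 * ((x - 0.45) * (x - 0.95))^2
  centers <- seq(0.3, 1.15, by = 0.05)
  set.seed(11)
  wins <- lapply(centers, function(c0) {
    # Metropolis sampling of the biased density (independent oracle
    # path: direct MCMC on U + bias, not the package sampler)
    n_keep <- 6000
    x <- c0
    out <- numeric(n_keep)
    lp <- function(v) -(U(v) + 0.5 * 6000 * (v - c0)^2) / kT
    cur <- lp(x)
    for (i in seq_len(300 + n_keep * 5)) {
      xp <- x + rnorm(1, 0, 0.02)
      lpp <- lp(xp)
      if (log(runif(1)) < lpp - cur) { x <- xp; cur <- lpp }
      if (i > 300 && (i - 300) %% 5 == 0) out[(i - 300) / 5] <- x
    }
    umbrella_window(c0, 6000, out, 298)
  })
  bp <- bootstrap_pmf(wins, n_boot = 40, rng_seed = 3,
                      burn_in_fraction = 0, grid_spacing = 0.01)
  sel <- is.finite(bp$pmf) & bp$r >= 0.35 & bp$r <= 1.05 & !is.na(bp$err)
  truth <- U(bp$r[sel])
  truth <- truth - mean(truth)         # compare up to the free constant
  pm <- bp$pmf[sel] - mean(bp$pmf[sel])
  expect_lt(sqrt(mean((pm - truth)^2)), 0.5)
  covered <- abs(pm - truth) <= 2 * pmax(bp$err[sel], 0.05)
  expect_gte(mean(covered), 0.9)
})

test_that("well depth extraction handles flat, shaped and edge cases", {
  flat <- data.frame(r = seq(0.1, 1, 0.01), pmf = 0, err = NA)
  expect_equal(well_depth(flat, c(0.9, 1))$depth, 0)
  r <- seq(0.1, 1.5, 0.005)
  gauss <- data.frame(r = r, pmf = -8 * exp(-(r - 0.5)^2 / (2 * 0.05^2)),
                      err = NA)
  wd <- well_depth(gauss, c(1.3, 1.5))
  expect_equal(wd$depth, -8, tolerance = 1e-3)
  expect_equal(wd$location, 0.5, tolerance = 0.005)
  expect_false(wd$at_edge)
  # deeper well -> more negative depth (monotone)
  d2 <- well_depth(
    data.frame(r = r, pmf = -12 * exp(-(r - 0.5)^2 / 0.005), err = NA),
    c(1.3, 1.5))$depth
  expect_lt(d2, wd$depth)
  # minimum at edge is flagged
  slope <- data.frame(r = r, pmf = r, err = NA)
  expect_true(well_depth(slope, c(1.3, 1.5))$at_edge)
})
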