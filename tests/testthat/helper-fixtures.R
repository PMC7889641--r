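# Shared fixtures, built in code at test time.

hps <- load_residue_params()

# A 50-residue PLD-like benchmark: sticky (Tyr/Ser/Gly) with sparse
# opposite charges and cation-pi donors/acceptors, the reduced stand-in
# for a FUS-like protein in desk-scale coexistence runs.
fus_like_seq <- function(n_repeats = 5) {
  paste(rep("SYGRGYDGSY", n_repeats), collapse = "")
}

pr25_seq <- function() make_sequence("PR25")

# Minimal hand-built trajectory: fixed bead positions over `n_frames`
# identical frames (for contact/profile oracles).
manual_trajectory <- function(positions, chain, box, n_frames = 1,
                              masses = NULL, codes = NULL) {
  n <- nrow(positions)
  frames <- array(0, dim = c(3, n, n_frames))
  for (f in seq_len(n_frames)) frames[, , f] <- t(positions)
  beads <- data.frame(
    chain = chain, resindex = stats::ave(chain, chain, FUN = seq_along),
    code = if (is.null(codes)) rep("G", n) else codes,
    mass = if (is.null(masses)) rep(100, n) else masses,
    charge = 0, sigma = 0.5, lambda = 0.5, buried = FALSE,
    cation = FALSE, aromatic = FALSE, species = "manual")
  structure(list(frames = frames, frame_time_ps = seq_len(n_frames),
                 energy_log = data.frame(), box = box, beads = beads,
                 temperature = 300,
                 scaling = interaction_scaling(), seed = 1, dt_fs = 10,
                 thin = 1),
            class = "slab_trajectory")
}

# Analytic double-tanh slab profile used as the coexistence oracle.
tanh_profile <- function(rho_den = 300, rho_dil = 3, L = 20, n_bins = 80,
                         w = 5, d = 0.5, masses_total = NULL) {
  z <- seq(L / n_bins / 2, L - L / n_bins / 2, length.out = n_bins)
  rho <- rho_dil + (rho_den - rho_dil) / 2 *
    (tanh((z - L / 2 + w / 2) / d) - tanh((z - L / 2 - w / 2) / d))
  out <- data.frame(z = z, density = rho)
  attr(out, "bin_volume") <- 25 * L / n_bins
  attr(out, "frames_used") <- 1
  attr(out, "axis") <- 3
  attr(out, "box") <- c(5, 5, L)
  attr(out, "total_mass") <- sum(rho * 25 * L / n_bins) / 1.66053907
  class(out) <- c("density_profile", "data.frame")
  out
}

# Exact Gaussian sampling from a harmonic potential U = k/2 (x - x0)^2
# biased by a harmonic umbrella: the closed-form oracle for WHAM.
harmonic_windows <- function(k_true = 50, x0 = 0.8, centers = seq(0.3, 1.3, 0.1),
                             k_bias = 1000, n = 50000, temperature = 298,
                             seed = 7) {
  kT <- 8.31446e-3 * temperature
  set.seed(seed)
  lapply(centers, function(c0) {
    prec <- (k_true + k_bias) / kT
    mu <- (k_true * x0 + k_bias * c0) / (k_true + k_bias)
    umbrella_window(c0, k_bias, rnorm(n, mu, sqrt(1 / prec)), temperature)
  })
}
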