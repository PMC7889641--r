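#' Toy salt-dependent pair potential classes
#'
#' Closed-form stand-ins for atomistic pair PMFs, encoding only the
#' qualitative salt trends observed for amino-acid pairs: a screened
#' Coulomb term whose decay length is the Debye length at the given
#' salt, plus a Gaussian hydrophobic well whose depth grows linearly
#' with salt (salting-out), on top of a steep repulsive core.
#'
#' Classes: `charged_opposite` (attraction, screened away by salt),
#' `charged_like_pi` (Arg-Arg-like: repulsive at low salt, attractive
#' once screened), `hydrophobic` (well deepens with salt),
#' `cation_pi_hybrid` (strong at both extremes, dip in between allowed).
#'
#' @param cls Class name.
#' @param coul_pref Bare Coulomb prefactor, kJ nm/mol (sign sets
#'   attraction/repulsion); class default if NULL.
#' @param depth0 Hydrophobic well depth at zero salt, kJ/mol (>= 0).
#' @param salt_coef Salting-out coefficient, kJ/mol per mol/L (>= 0).
#' @param well_center,well_width Gaussian well centre and width, nm.
#' @return A `toy_pair_class` parameter list.
#' @export
toy_pair_class <- function(cls = c("charged_opposite", "charged_like_pi",
                                   "hydrophobic", "cation_pi_hybrid"),
                           coul_pref = NULL, depth0 = NULL,
                           salt_coef = NULL, well_center = 0.5,
                           well_width = 0.12) {
  cls <- match.arg(cls)
  defaults <- switch(cls,
    charged_opposite = list(coul = -2.0, d0 = 2.0, sc = 0.0),
    charged_like_pi  = list(coul = +2.0, d0 = 1.0, sc = 2.0),
    hydrophobic      = list(coul = 0.0,  d0 = 3.0, sc = 2.0),
    cation_pi_hybrid = list(coul = -1.5, d0 = 3.0, sc = 1.5))
  if (is.null(coul_pref)) coul_pref <- defaults$coul
  if (is.null(depth0)) depth0 <- defaults$d0
  if (is.null(salt_coef)) salt_coef <- defaults$sc
  if (well_width <= 0) stop("well width must be > 0")
  if (salt_coef < 0) stop("salting-out coefficient must be >= 0")
  structure(list(cls = cls, coul_pref = coul_pref, depth0 = depth0,
                 salt_coef = salt_coef, well_center = well_center,
                 well_width = well_width),
            class = "toy_pair_class")
}

#' Evaluate a toy pair potential
#'
#' @param r Separation(s), nm (> 0).
#' @param cls A `toy_pair_class`.
#' @param salt NaCl concentration, mol/L (>= 0).
#' @param temperature K (sets the Debye length).
#' @return U(r) in kJ/mol (vectorized over `r`).
#' @export
toy_pair_potential <- function(r, cls, salt, temperature = 298) {
  if (any(r <= 0)) stop("r must be > 0")
  if (salt < 0) stop("negative salt concentration")
  stopifnot(inherits(cls, "toy_pair_class"))
  lam_d <- debye_length(salt, temperature)
  core <- 0.2 * (0.30 / r)^12
  elec <- cls$coul_pref * exp(-r / lam_d) / r
  depth <- cls$depth0 + cls$salt_coef * salt
  hydro <- -depth * exp(-(r - cls$well_center)^2 / (2 * cls$well_width^2))
  core + elec + hydro
}

#' Sample umbrella windows from a toy pair potential
#'
#' Exact 1-D Metropolis sampling from `exp(-(U + bias)/kBT)` per window,
#' run as many parallel chains and thinned toward independence.
#' Seed-deterministic.
#'
#' @param cls A `toy_pair_class`.
#' @param salt mol/L.
#' @param centers Bias centres, nm (sorted; default the reference
#'   protocol's 0.1-1.6 nm at 0.05 nm spacing).
#' @param k_bias Bias force constant, kJ/mol/nm^2 (default 6000).
#' @param n_per_window Samples kept per window.
#' @param temperature K.
#' @param rng_seed Integer seed.
#' @param thin Metropolis steps between kept samples (default 5).
#' @param n_chains Parallel chains per window (default 64).
#' @return List of `umbrella_window`s.
#' @export
sample_umbrella_windows <- function(cls, salt,
                                    centers = seq(0.1, 1.6, by = 0.05),
                                    k_bias = 6000, n_per_window = 5000,
                                    temperature = 298, rng_seed = 1,
                                    thin = 5, n_chains = 64) {
  stopifnot(inherits(cls, "toy_pair_class"), k_bias > 0,
            !is.unsorted(centers))
  kT <- .kB * temperature
  prop_sd <- max(0.01, 0.7 * sqrt(kT / k_bias))
  set.seed(rng_seed)
  out <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    c0 <- centers[w]
    logp <- function(x) {
      v <- rep(-Inf, length(x))
      ok <- x > 0.02
      v[ok] <- -(toy_pair_potential(x[ok], cls, salt, temperature) +
                   0.5 * k_bias * (x[ok] - c0)^2) / kT
      v
    }
    x <- pmax(rep(c0, n_chains) + rnorm(n_chains, 0, prop_sd), 0.05)
    lp <- logp(x)
    n_keep_rounds <- ceiling(n_per_window / n_chains)
    burn <- 200
    acc <- 0; tries <- 0
    kept <- matrix(NA_real_, n_chains, n_keep_rounds)
    round_i <- 0
    for (it in seq_len(burn + n_keep_rounds * thin)) {
      xp <- x + rnorm(n_chains, 0, prop_sd)
      lpp <- logp(xp)
      a <- log(runif(n_chains)) < lpp - lp
      x[a] <- xp[a]
      lp[a] <- lpp[a]
      acc <- acc + sum(a); tries <- tries + n_chains
      if (it > burn && (it - burn) %% thin == 0) {
        round_i <- round_i + 1
        kept[, round_i] <- x
      }
    }
    if (acc / tries < 1e-3) {
      stop("Metropolis acceptance ~0 in window at ", c0,
           " nm; pathological bias constant")
    }
    out[[w]] <- umbrella_window(c0, k_bias,
                                as.numeric(kept)[seq_len(n_per_window)],
                                temperature)
  }
  out
}

#' Benchmark protein sequences
#'
#' `PR25` is the 25-residue proline-arginine repeat peptide (13 Arg and
#' 12 Pro alternating, Arg at both termini).  `FUS_PLD` is the first 163
#' residues (the prion-like domain) of a user-supplied full-length FUS
#' FASTA (UniProt K7DPS7, 526 residues); `FUS_full` is the full supplied
#' sequence.  `homopolymer` is `n` copies of residue `res`.
#'
#' @param kind One of `"PR25"`, `"FUS_PLD"`, `"FUS_full"`,
#'   `"homopolymer"`.
#' @param fasta_path FASTA path (required for the FUS kinds).
#' @param res,n Residue and length for `homopolymer`.
#' @return Sequence string.
#' @export
make_sequence <- function(kind = c("PR25", "FUS_PLD", "FUS_full",
                                   "homopolymer"),
                          fasta_path = NULL, res = "A", n = 50) {
  kind <- match.arg(kind)
  if (kind == "PR25") {
    return(paste0(strrep("RP", 12), "R"))
  }
  if (kind == "homopolymer") {
    if (!(res %in% AA_CODES)) stop("unknown residue code: ", res)
    return(strrep(res, n))
  }
  if (is.null(fasta_path)) {
    stop(kind, " requires a user-supplied FASTA of full-length FUS ",
         "(UniProt accession K7DPS7)")
  }
  seqs <- read_fasta(fasta_path)
  full <- seqs[[1]]
  if (kind == "FUS_full") return(full)
  if (nchar(full) < 163) {
    stop("supplied FUS sequence has fewer than 163 residues")
  }
  substr(full, 1, 163)
}

#' Synthetic coexistence points from the critical scaling law
#'
#' Generates subcritical coexistence points with
#' `rho_dense - rho_dilute = A (1 - T/Tc)^beta` split symmetrically
#' about a linear rectilinear diameter, plus optional multiplicative
#' Gaussian noise.  The closed-loop oracle for [fit_critical_point()].
#'
#' @param Tc Critical temperature, K.
#' @param A Order-parameter amplitude, mg/mL.
#' @param beta Critical exponent (default 0.325).
#' @param temps Temperatures, K (all < Tc).
#' @param noise_sd Relative (fractional) Gaussian noise on each density.
#' @param rng_seed Integer seed.
#' @param rho_c Critical density, mg/mL.
#' @param diam_slope Rectilinear-diameter slope, mg/mL/K.
#' @return List of `coexistence_point`-like lists with `temperature`,
#'   `rho_dilute`, `rho_dense`.
#' @export
synth_coexistence_points <- function(Tc, A, beta = 0.325, temps,
                                     noise_sd = 0, rng_seed = 1,
                                     rho_c = 300, diam_slope = 0.5) {
  if (any(temps >= Tc)) stop("all temperatures must be below Tc")
  set.seed(rng_seed)
  lapply(temps, function(Tk) {
    d_rho <- A * (1 - Tk / Tc)^beta
    diam <- rho_c + diam_slope * (Tc - Tk)
    den <- diam + d_rho / 2
    dil <- max(diam - d_rho / 2, 0)
    if (noise_sd > 0) {
      den <- den * (1 + rnorm(1, 0, noise_sd))
      dil <- max(dil * (1 + rnorm(1, 0, noise_sd)), 0)
    }
    structure(list(temperature = Tk, rho_dilute = dil, rho_dense = den),
              class = "coexistence_point")
  })
}

#' Synthetic labeled droplet mask
#'
#' Rasterizes non-touching disks (optionally with smooth low-order
#' boundary perturbations) into an integer label mask, returning the
#' analytic ground truth alongside.
#'
#' @param radii_px Disk radii, px.
#' @param positions N x 2 matrix of centres (px), or NULL for an
#'   automatic grid layout.
#' @param image_size Length-2 image dimensions, px.
#' @param boundary_noise Relative amplitude of the radial perturbation
#'   (0 = perfect disks).
#' @param rng_seed Integer seed.
#' @return List with `mask` (integer matrix, 0 background) and `truth`
#'   (data frame `label`, `radius_px`, `area_px` analytic pi r^2,
#'   `cx`, `cy`).
#' @export
synth_droplet_mask <- function(radii_px, positions = NULL,
                               image_size = c(256, 256),
                               boundary_noise = 0, rng_seed = 1) {
  nd <- length(radii_px)
  set.seed(rng_seed)
  if (is.null(positions)) {
    ng <- ceiling(sqrt(nd))
    gx <- image_size[1] / (ng + 0)
    centres <- expand.grid(ix = seq_len(ng), iy = seq_len(ng))[seq_len(nd), ]
    positions <- cbind((centres$ix - 0.5) * gx,
                       (centres$iy - 0.5) * image_size[2] / ng)
  }
  positions <- as.matrix(positions)
  for (a in seq_len(nd)) {
    if (positions[a, 1] - radii_px[a] < 1 ||
        positions[a, 1] + radii_px[a] > image_size[1] ||
        positions[a, 2] - radii_px[a] < 1 ||
        positions[a, 2] + radii_px[a] > image_size[2]) {
      stop("droplet ", a, " extends outside the frame")
    }
    for (b in seq_len(a - 1)) {
      dd <- sqrt(sum((positions[a, ] - positions[b, ])^2))
      if (dd <= radii_px[a] + radii_px[b] + 2) {
        stop("droplets ", b, " and ", a, " touch or overlap")
      }
    }
  }
  mask <- matrix(0L, image_size[1], image_size[2])
  xx <- matrix(seq_len(image_size[1]), image_size[1], image_size[2])
  yy <- matrix(seq_len(image_size[2]), image_size[1], image_size[2],
               byrow = TRUE)
  for (a in seq_len(nd)) {
    dx <- xx - positions[a, 1]
    dy <- yy - positions[a, 2]
    rr <- sqrt(dx^2 + dy^2)
    if (boundary_noise > 0) {
      th <- atan2(dy, dx)
      amp <- rnorm(3, 0, boundary_noise)
      ph <- runif(3, 0, 2 * pi)
      pert <- amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]) +
        amp[3] * sin(4 * th + ph[3])
      r_eff <- radii_px[a] * (1 + pert)
    } else {
      r_eff <- radii_px[a]
    }
    mask[rr <= r_eff] <- a
  }
  truth <- data.frame(label = seq_len(nd), radius_px = radii_px,
                      area_px = pi * radii_px^2,
                      cx = positions[, 1], cy = positions[, 2])
  list(mask = mask, truth = truth)
}
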