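#' Mass density profile along the slab axis
#'
#' Time-averaged mass density per bin along the box long axis.  Each
#' frame is recentred so the dense-phase centre of mass (computed with
#' the circular-mean construction appropriate for periodic coordinates)
#' sits at the box centre before binning; this prevents interface
#' smearing from slab drift.  The profile conserves total mass exactly:
#' sum(density * bin volume) equals the system mass.
#'
#' @param traj A `slab_trajectory`.
#' @param axis Axis index (1-3); default the longest box edge.
#' @param n_bins Number of bins (>= 10).
#' @param equil_fraction Fraction of initial frames discarded.
#' @return A `density_profile` data frame with `z` (bin centres, nm) and
#'   `density` (mg/mL), plus attributes `bin_volume`, `frames_used`,
#'   `axis`, `box`, `total_mass`.
#' @export
density_profile <- function(traj, axis = which.max(traj$box),
                            n_bins = 60, equil_fraction = 0.3) {
  stopifnot(inherits(traj, "slab_trajectory"), n_bins >= 10,
            equil_fraction >= 0, equil_fraction < 1)
  n_frames <- dim(traj$frames)[3]
  first <- floor(equil_fraction * n_frames) + 1
  if (first > n_frames) stop("no frames left after equilibration cut")
  use <- first:n_frames
  L <- traj$box[axis]
  edges <- seq(0, L, length.out = n_bins + 1)
  bin_volume <- prod(traj$box[-axis]) * (L / n_bins)
  mass <- traj$beads$mass
  counts <- numeric(n_bins)
  for (f in use) {
    zc <- traj$frames[axis, , f] %% L
    # circular mean of mass-weighted positions -> slab centre
    theta <- zc / L * 2 * pi
    ang <- atan2(sum(mass * sin(theta)), sum(mass * cos(theta)))
    centre <- (ang / (2 * pi)) %% 1 * L
    z <- (zc - centre + L / 2) %% L
    b <- pmin(pmax(floor(z / L * n_bins) + 1, 1), n_bins)
    counts <- counts + tapply(mass, factor(b, levels = seq_len(n_bins)),
                              sum, default = 0)
  }
  dens <- counts / length(use) / bin_volume * .DENS_TO_MGML
  out <- data.frame(z = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    density = as.numeric(dens))
  attr(out, "bin_volume") <- bin_volume
  attr(out, "frames_used") <- length(use)
  attr(out, "axis") <- axis
  attr(out, "box") <- traj$box
  attr(out, "total_mass") <- sum(mass)
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Coexistence densities from a slab density profile
#'
#' Fits a symmetric double-hyperbolic-tangent step
#' `rho(z) = rho_dil + (rho_den - rho_dil)/2 * (tanh((z - c + w/2)/d) -
#' tanh((z - c - w/2)/d))` to a recentred profile.  Plateau densities are
#' the fitted `rho_den` and `rho_dil`; if the fit does not converge the
#' function falls back to central-20% / outer-20% bin averages and flags
#' the point.
#'
#' @param profile A `density_profile`.
#' @return A `coexistence_point` list: `temperature` (NA unless set by
#'   the caller), `rho_dilute`, `rho_dense` (mg/mL), `interface_width`
#'   (nm), `uncertainty` (per-density, mg/mL), `fit_ok`.
#' @export
coexistence_densities <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z
  rho <- profile$density
  L <- max(z) + z[1]
  n <- length(z)
  centre_idx <- abs(z - L / 2) <= L * 0.1
  outer_idx <- z <= L * 0.1 | z >= L * 0.9
  rho_den0 <- mean(rho[centre_idx])
  rho_dil0 <- mean(rho[outer_idx])
  w0 <- L / 4

  fit <- tryCatch({
    df <- data.frame(z = z, rho = rho)
    m <- minpack.lm::nlsLM(
      rho ~ rd + (rc - rd) / 2 *
        (tanh((z - L / 2 + w / 2) / d) - tanh((z - L / 2 - w / 2) / d)),
      data = df,
      start = list(rd = max(rho_dil0, 0), rc = rho_den0, w = w0,
                   d = L / 30),
      lower = c(0, 0, L / 100, L / 1000),
      upper = c(Inf, Inf, L, L),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(m)
  }, error = function(e) NULL)

  if (!is.null(fit) && fit[["rc"]] >= fit[["rd"]]) {
    rho_dense <- fit[["rc"]]
    rho_dilute <- fit[["rd"]]
    width <- fit[["d"]]
    # plateau scatter excluding interface bins
    c_lo <- L / 2 - fit[["w"]] / 2
    c_hi <- L / 2 + fit[["w"]] / 2
    in_dense <- z > c_lo + 2 * width & z < c_hi - 2 * width
    in_dil <- z < c_lo - 2 * width | z > c_hi + 2 * width
    unc <- c(dense = if (sum(in_dense) > 1) sd(rho[in_dense]) else NA_real_,
             dilute = if (sum(in_dil) > 1) sd(rho[in_dil]) else NA_real_)
    fit_ok <- TRUE
  } else {
    rho_dense <- rho_den0
    rho_dilute <- rho_dil0
    width <- NA_real_
    unc <- c(dense = sd(rho[centre_idx]), dilute = sd(rho[outer_idx]))
    fit_ok <- FALSE
  }
  if (rho_dense < rho_dilute) { # uniform-profile noise can invert them
    tmp <- rho_dense; rho_dense <- rho_dilute; rho_dilute <- tmp
  }
  structure(list(temperature = NA_real_, rho_dilute = rho_dilute,
                 rho_dense = rho_dense, interface_width = width,
                 uncertainty = unc, fit_ok = fit_ok),
            class = "coexistence_point")
}

#' Classify liquid-liquid phase separation from coexistence densities
#'
#' TRUE iff `rho_dense / max(rho_dilute, floor) >= ratio_threshold`
#' (inclusive at the threshold).  The floor guards against division by
#' zero for empty dilute phases.
#'
#' @param point A `coexistence_point` (or list with `rho_dense`,
#'   `rho_dilute`).
#' @param ratio_threshold Density ratio defining LLPS (default 10).
#' @param floor Dilute-density floor, mg/mL (default 1e-3).
#' @return Logical.
#' @export
classify_llps <- function(point, ratio_threshold = 10, floor = 1e-3) {
  point$rho_dense / max(point$rho_dilute, floor) >= ratio_threshold
}

#' Critical-point fit from subcritical coexistence points
#'
#' Simultaneous least-squares fit of the order-parameter scaling law
#' `rho_dense - rho_dilute = A * (1 - T/Tc)^beta` (3D Ising beta =
#' 0.325, fixed) and the law of rectilinear diameters
#' `(rho_dense + rho_dilute)/2 = rho_c + s * (Tc - T)`.  For a given Tc
#' both relations are linear, so the profile over Tc is minimized by a
#' one-dimensional search; a bootstrap over points gives a Tc confidence
#' interval.
#'
#' @param points List of `coexistence_point`s (with `temperature` set),
#'   or a data frame with columns `temperature`, `rho_dilute`,
#'   `rho_dense`.
#' @param beta Critical exponent (default 0.325; overridable).
#' @param n_boot Bootstrap replicates for the Tc CI (default 200).
#' @param conf Confidence level (default 0.95).
#' @param rng_seed Seed for the bootstrap resampling.
#' @return A `critical_fit` list: `Tc`, `A`, `beta`, `rho_c`, `slope`,
#'   `residuals`, `Tc_ci` (two-sided basic bootstrap interval) and
#'   `Tc_boot` (replicate values).
#' @export
fit_critical_point <- function(points, beta = 0.325, n_boot = 200,
                               conf = 0.95, rng_seed = 1) {
  df <- if (is.data.frame(points)) points else do.call(rbind, lapply(
    points, function(p) data.frame(temperature = p$temperature,
                                   rho_dilute = p$rho_dilute,
                                   rho_dense = p$rho_dense)))
  if (nrow(df) < 3) stop("need at least 3 subcritical coexistence points")
  d_rho <- df$rho_dense - df$rho_dilute
  if (all(d_rho <= 0)) stop("all density differences are zero")
  Tv <- df$temperature

  fit_at <- function(Tc, Tvv, drho, diam) {
    x1 <- pmax(1 - Tvv / Tc, 0)^beta
    A <- sum(x1 * drho) / sum(x1 * x1)
    X <- cbind(1, Tc - Tvv)
    cf <- tryCatch(qr.solve(X, diam), error = function(e) c(mean(diam), 0))
    ss <- sum((drho - A * x1)^2) + sum((diam - X %*% cf)^2)
    list(ss = ss, A = A, rho_c = cf[1], slope = cf[2])
  }
  solve_tc <- function(Tvv, drho, diam) {
    Tmax <- max(Tvv)
    dT <- if (length(unique(Tvv)) > 1) min(diff(sort(unique(Tvv)))) else
      0.05 * Tmax
    opt <- optimize(function(Tc) fit_at(Tc, Tvv, drho, diam)$ss,
                    lower = Tmax + 1e-6 * Tmax, upper = Tmax + 20 * dT,
                    tol = 1e-6 * Tmax)
    opt$minimum
  }

  diam <- (df$rho_dense + df$rho_dilute) / 2
  Tc <- solve_tc(Tv, d_rho, diam)
  best <- fit_at(Tc, Tv, d_rho, diam)

  Tc_boot <- rep(NA_real_, n_boot)
  if (n_boot >= 2) {
    set.seed(rng_seed)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(df), replace = TRUE)
      if (length(unique(Tv[idx])) < 3) idx <- seq_len(nrow(df))
      Tc_boot[b] <- tryCatch(
        solve_tc(Tv[idx], d_rho[idx], diam[idx]),
        error = function(e) NA_real_)
    }
  }
  # basic (reflected) bootstrap interval: better calibrated than the
  # percentile interval for this skewed, small-sample estimator
  alpha <- (1 - conf) / 2
  ci <- if (all(is.na(Tc_boot))) c(NA_real_, NA_real_) else {
    qs <- quantile(Tc_boot, c(1 - alpha, alpha), na.rm = TRUE,
                   names = FALSE)
    2 * Tc - qs
  }

  x1 <- pmax(1 - Tv / Tc, 0)^beta
  resid <- c(d_rho - best$A * x1,
             diam - best$rho_c - best$slope * (Tc - Tv))
  structure(list(Tc = Tc, A = best$A, beta = beta, rho_c = best$rho_c,
                 slope = best$slope, residuals = resid, Tc_ci = ci,
                 Tc_boot = Tc_boot),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat("critical_fit: Tc = ", signif(x$Tc, 5), " K (",
      signif(x$Tc_ci[1], 5), "-", signif(x$Tc_ci[2], 5),
      "), A = ", signif(x$A, 4), " mg/mL, beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Phase-diagram scan over interaction regimes
#'
#' Runs a reduced direct-coexistence simulation for every row of a
#' condition grid, extracts coexistence densities and classifies LLPS by
#' majority vote over seeds (single-seed calls are flagged
#' low-confidence).
#'
#' @param systems Named list; each element a list with `topology` (or
#'   list of topologies), `counts`, `box`, and optionally
#'   `protein_class`.
#' @param conditions Data frame with columns `system` (name into
#'   `systems`), `regime` (preset name, see [apply_regime()]) and
#'   `temperature` (K).  Alternatively a `scaling` list-column of
#'   explicit `interaction_scaling` objects.
#' @param params A `residue_params` table.
#' @param n_steps,thin,slab_fraction,equil_fraction Simulation/analysis
#'   controls.
#' @param seeds Integer vector of seeds (majority vote; use >= 3 for a
#'   confident call).
#' @param ratio_threshold Passed to [classify_llps()].
#' @return Tidy data frame: one row per condition with `rho_dilute`,
#'   `rho_dense` (seed medians), `llps` (majority), `votes`,
#'   `low_confidence`.
#' @export
scan_phase_diagram <- function(systems, conditions, params,
                               n_steps = 100000, thin = 1000,
                               slab_fraction = 0.25, equil_fraction = 0.5,
                               seeds = 1:3, ratio_threshold = 10) {
  rows <- vector("list", nrow(conditions))
  for (r in seq_len(nrow(conditions))) {
    cond <- conditions[r, , drop = FALSE]
    sys <- systems[[cond$system]]
    scal <- if (!is.null(conditions$scaling)) {
      conditions$scaling[[r]]
    } else {
      apply_regime(cond$regime,
                   if (is.null(sys$protein_class)) "fus_like" else
                     sys$protein_class,
                   temperature = cond$temperature)
    }
    votes <- logical(length(seeds))
    rdil <- rden <- numeric(length(seeds))
    for (s in seq_along(seeds)) {
      st <- init_slab(sys$topology, sys$counts, sys$box, params,
                      slab_fraction = slab_fraction, rng_seed = seeds[s])
      traj <- langevin_run(st, scal, cond$temperature, n_steps = n_steps,
                           thin = thin, rng_seed = seeds[s])
      prof <- density_profile(traj, equil_fraction = equil_fraction)
      pt <- coexistence_densities(prof)
      votes[s] <- classify_llps(pt, ratio_threshold)
      rdil[s] <- pt$rho_dilute
      rden[s] <- pt$rho_dense
    }
    rows[[r]] <- data.frame(
      system = cond$system,
      regime = if (!is.null(cond$regime)) cond$regime else NA_character_,
      temperature = cond$temperature,
      rho_dilute = median(rdil), rho_dense = median(rden),
      llps = mean(votes) > 0.5, votes = sum(votes),
      n_seeds = length(seeds),
      low_confidence = length(seeds) < 3,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
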