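#' Umbrella-sampling window
#'
#' One biased window of a 1-D reaction coordinate (here a pair
#' centre-of-mass distance): harmonic bias `0.5 * k * (x - center)^2`,
#' a vector of sampled coordinate values, and the sampling temperature.
#'
#' @param center Bias centre, nm.
#' @param k Bias force constant, kJ/mol/nm^2 (> 0; the reference
#'   protocol uses 6000).
#' @param samples Reaction-coordinate samples, nm (finite, >= 1).
#' @param temperature K.
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, temperature = 298) {
  if (!(k > 0)) stop("bias force constant must be > 0")
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("window needs at least one sample")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(center = center, k = k, samples = samples,
                 temperature = temperature),
            class = "umbrella_window")
}

#' Write / read umbrella windows in the plain-text window format
#'
#' One file per window: a header line `center_nm,k_kj_mol_nm2,
#' temperature_K` with its values on the second line, then one sample
#' per line.
#'
#' @param window An `umbrella_window`.
#' @param path File path.
#' @export
write_window <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("center_nm,k_kj_mol_nm2,temperature_K", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", window$center, window$k,
                     window$temperature), con)
  writeLines(sprintf("%.10g", window$samples), con)
  invisible(path)
}

#' @rdname write_window
#' @export
read_window <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("window file too short: ", path)
  hdr <- as.numeric(strsplit(lines[2], ",", fixed = TRUE)[[1]])
  umbrella_window(hdr[1], hdr[2], as.numeric(lines[-(1:2)]), hdr[3])
}

#' Read a manifest of umbrella-window files
#'
#' The manifest lists one window file per line (paths relative to the
#' manifest's directory unless absolute); blank lines and `#` comments
#' are skipped.
#'
#' @param path Manifest file path.
#' @return List of `umbrella_window`s, ready for [wham_solve()].
#' @export
read_window_manifest <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("manifest lists no window files: ", path)
  base <- dirname(path)
  lapply(lines, function(f) {
    full <- if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
    read_window(full)
  })
}

# Shared grid/histogram setup.
.wham_setup <- function(windows, grid, burn_in_fraction, grid_spacing) {
  windows <- lapply(windows, function(w) {
    n0 <- floor(burn_in_fraction * length(w$samples))
    if (n0 > 0 && n0 < length(w$samples)) {
      w$samples <- w$samples[-seq_len(n0)]
    }
    w
  })
  if (is.null(grid)) {
    rng <- range(unlist(lapply(windows, function(w) range(w$samples))))
    grid <- seq(rng[1] - grid_spacing / 2, rng[2] + grid_spacing / 2,
                by = grid_spacing)
  }
  h <- grid[2] - grid[1]
  edges <- c(grid - h / 2, grid[length(grid)] + h / 2)
  counts <- vapply(windows, function(w) {
    b <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(b[b >= 1 & b <= length(grid)], nbins = length(grid))
  }, integer(length(grid)))
  list(windows = windows, grid = grid, counts = counts, h = h)
}

#' Weighted-histogram (WHAM) reconstruction of a 1-D PMF
#'
#' Standard self-consistent WHAM over harmonic umbrella windows: window
#' free energies f_k and the unbiased density are iterated until
#' `max |delta f_k| < tol`; the PMF is `-kB T log(density)`, zeroed over
#' the reference range (by default the largest 10% of the grid, where
#' pair PMFs plateau to zero).
#'
#' @param windows List of `umbrella_window`s (overlapping histograms).
#' @param grid Optional grid of coordinate values, nm; default uniform
#'   at `grid_spacing` over the union of window supports.
#' @param grid_spacing Default grid spacing, nm (0.005).
#' @param tol Convergence tolerance on f_k changes, kJ/mol.
#' @param max_iter Iteration cap.
#' @param burn_in_fraction Fraction of each window's initial samples
#'   discarded as equilibration (default 0.1, mirroring the reference
#'   protocol's dropped first nanosecond).
#' @param reference_range Range (nm, length-2) over which the PMF is
#'   zeroed; default the largest 10% of the grid.
#' @param window_weights Optional per-window multiplicative weights
#'   (used by the Bayesian bootstrap); default all 1.
#' @return A `pmf_profile` data frame with columns `r` (nm), `pmf`
#'   (kJ/mol; +Inf where unsampled) and `err` (NA until
#'   [bootstrap_pmf()] fills it), with attributes `f_k`, `iterations`,
#'   `converged`, `kT`, `reference_range`.
#' @export
wham_solve <- function(windows, grid = NULL, grid_spacing = 0.005,
                       tol = 1e-7, max_iter = 1e5,
                       burn_in_fraction = 0.1, reference_range = NULL,
                       window_weights = NULL) {
  stopifnot(length(windows) >= 1)
  setup <- .wham_setup(windows, grid, burn_in_fraction, grid_spacing)
  grid <- setup$grid
  counts <- setup$counts
  K <- length(setup$windows)
  temperature <- setup$windows[[1]]$temperature
  kT <- .kB * temperature

  # island detection: the windows' sampled ranges must form one
  # connected union, otherwise WHAM cannot tie their free energies
  rngs <- t(vapply(setup$windows, function(w) range(w$samples),
                   numeric(2)))
  ord <- order(rngs[, 1])
  islands <- list(rngs[ord[1], ])
  members <- list(ord[1])
  for (k in ord[-1]) {
    cur <- islands[[length(islands)]]
    if (rngs[k, 1] <= cur[2] + setup$h) {
      islands[[length(islands)]] <- c(cur[1], max(cur[2], rngs[k, 2]))
      members[[length(members)]] <- c(members[[length(members)]], k)
    } else {
      islands[[length(islands) + 1]] <- rngs[k, ]
      members[[length(members) + 1]] <- k
    }
  }
  if (length(islands) > 1) {
    desc <- vapply(seq_along(islands), function(a) {
      sprintf("[%.3f, %.3f] (windows %s)", islands[[a]][1],
              islands[[a]][2],
              paste(sort(members[[a]]), collapse = ","))
    }, character(1))
    stop("umbrella windows do not overlap; sampled ranges form ",
         length(islands), " disconnected islands: ",
         paste(desc, collapse = ", "))
  }

  g <- if (is.null(window_weights)) rep(1, K) else window_weights
  centers <- vapply(setup$windows, `[[`, numeric(1), "center")
  ks <- vapply(setup$windows, `[[`, numeric(1), "k")
  W <- 0.5 * outer(grid, centers, "-")^2 %*% diag(ks, K) # n_bins x K bias
  expW <- exp(-W / kT)
  Neff <- g * colSums(counts)
  tot <- as.numeric(counts %*% g)

  f <- numeric(K)
  converged <- FALSE
  prev_res <- Inf
  damp <- 1
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    denom <- as.numeric(expW %*% (Neff * exp(f / kT)))
    rho <- ifelse(denom > 0, tot / denom, 0)
    Z <- as.numeric(crossprod(expW, rho))
    f_new <- -kT * log(Z)
    f_new <- f_new - f_new[1]
    res <- max(abs(f_new - f))
    if (!is.finite(res)) stop("WHAM iteration diverged (non-finite f_k)")
    if (res > prev_res * 1.5) damp <- 0.5 # damp on oscillation
    f <- f + damp * (f_new - f)
    if (res < tol) { converged <- TRUE; break }
    prev_res <- res
  }
  if (!converged) {
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", signif(prev_res, 3), " kJ/mol)")
  }
  denom <- as.numeric(expW %*% (Neff * exp(f / kT)))
  rho <- ifelse(denom > 0, tot / denom, 0)
  pmf <- ifelse(rho > 0, -kT * log(rho), Inf)

  if (is.null(reference_range)) {
    reference_range <- c(quantile(grid, 0.9, names = FALSE), max(grid))
  }
  ref_idx <- grid >= reference_range[1] & grid <= reference_range[2] &
    is.finite(pmf)
  if (!any(ref_idx)) stop("no finite PMF values in the reference range")
  pmf <- pmf - mean(pmf[ref_idx])

  out <- data.frame(r = grid, pmf = pmf, err = NA_real_)
  attr(out, "f_k") <- f
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "kT") <- kT
  attr(out, "reference_range") <- reference_range
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Bayesian-bootstrap error band for a WHAM PMF
#'
#' Per replicate, whole windows are reweighted by Dirichlet(1, ..., 1)
#' weights and WHAM is re-solved; the band is the pointwise standard
#' deviation of the replicate PMFs.  Seed-deterministic.
#'
#' @param windows List of `umbrella_window`s.
#' @param n_boot Number of replicates (>= 2; default 200).
#' @param rng_seed Integer seed.
#' @param ... Passed to [wham_solve()] (grid, tolerances, ...).
#' @return A `pmf_profile` (the full-data solution) whose `err` column
#'   holds the band; attribute `n_boot_ok` counts successful replicates.
#' @export
bootstrap_pmf <- function(windows, n_boot = 200, rng_seed = 1, ...) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  base <- wham_solve(windows, ...)
  K <- length(windows)
  set.seed(rng_seed)
  reps <- matrix(NA_real_, length(base$r), n_boot)
  failed <- 0
  for (b in seq_len(n_boot)) {
    w <- rgamma(K, 1, 1)
    w <- w / sum(w) * K
    rep_b <- tryCatch(
      wham_solve(windows, grid = base$r, window_weights = w, ...),
      error = function(e) NULL)
    if (is.null(rep_b)) failed <- failed + 1 else reps[, b] <- rep_b$pmf
  }
  if (failed > 0.2 * n_boot) {
    stop(failed, "/", n_boot, " bootstrap replicates failed")
  }
  finite_rows <- is.finite(base$pmf)
  err <- apply(reps, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x) >= 2) sd(x) else NA_real_
  })
  base$err <- ifelse(finite_rows, err, NA_real_)
  attr(base, "n_boot_ok") <- n_boot - failed
  base
}

#' Well depth of a PMF
#'
#' Depth is `min(PMF) - mean(PMF over the reference range)`; negative
#' depth means net attraction.  A minimum at the grid edge is flagged.
#'
#' @param pmf A `pmf_profile` (or data frame with `r`, `pmf`).
#' @param reference_range Range (nm) of the zero reference; defaults to
#'   the profile's stored reference range, else the largest 10% of r.
#' @return List `depth` (kJ/mol), `location` (nm), `at_edge` (logical).
#' @export
well_depth <- function(pmf, reference_range = NULL) {
  r <- pmf$r
  v <- pmf$pmf
  fin <- is.finite(v)
  if (!any(fin)) stop("PMF has no finite values")
  if (is.null(reference_range)) {
    reference_range <- attr(pmf, "reference_range")
  }
  if (is.null(reference_range)) {
    reference_range <- c(quantile(r, 0.9, names = FALSE), max(r))
  }
  ref <- fin & r >= reference_range[1] & r <= reference_range[2]
  ref_mean <- mean(v[ref])
  i_min <- which(fin)[which.min(v[fin])]
  interior <- which(fin)
  at_edge <- i_min == interior[1] || i_min == interior[length(interior)]
  list(depth = v[i_min] - ref_mean, location = r[i_min], at_edge = at_edge)
}
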