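#' Assemble a multi-chain bead system
#'
#' Expands chain topologies into a flat per-bead table (masses, charges,
#' diameters, hydrophobicities, buried flags, chain ids).  Beads are
#' numbered consecutively within each chain, which the force kernel
#' relies on to exclude bonded (i, i+1) pairs from nonbonded terms.
#'
#' @param topologies A `chain_topology` or list of them.
#' @param counts Integer copies of each topology (recycled).
#' @param params A `residue_params` table.
#' @return List with `beads` (data frame), `bonds` (data frame with
#'   0-based `i`, `j` plus `r0`, `k`) and `n` (bead count).
#' @keywords internal
make_system <- function(topologies, counts, params) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  counts <- rep_len(as.integer(counts), length(topologies))
  beads <- list()
  bonds <- list()
  offset <- 0L
  chain_id <- 0L
  for (t in seq_along(topologies)) {
    topo <- topologies[[t]]
    codes <- strsplit(topo$sequence, "", fixed = TRUE)[[1]]
    idx <- match(codes, params$res)
    for (c in seq_len(counts[t])) {
      chain_id <- chain_id + 1L
      beads[[chain_id]] <- data.frame(
        chain = chain_id,
        resindex = seq_along(codes),
        code = codes,
        mass = params$mass[idx],
        charge = params$charge[idx],
        sigma = params$sigma[idx],
        lambda = params$lambda[idx],
        buried = topo$buried,
        cation = params$is_cation[idx],
        aromatic = params$is_aromatic[idx],
        species = topo$name,
        stringsAsFactors = FALSE)
      if (nrow(topo$bonds) > 0) {
        bonds[[chain_id]] <- data.frame(
          i = topo$bonds$i - 1L + offset,
          j = topo$bonds$j - 1L + offset,
          r0 = topo$bonds$r0, k = topo$bonds$k)
      }
      offset <- offset + topo$length
    }
  }
  beads <- do.call(rbind, beads)
  bonds <- if (length(bonds) > 0) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
               k = numeric(0))
  list(beads = beads, bonds = bonds, n = nrow(beads))
}

# Effective per-bead arrays handed to the C++ kernel.  The buried 0.7
# scale-down and the regime hydro_scale both multiply per-residue lambda,
# so the arithmetic pair mean reproduces lambda_ij of the model.
.bead_arrays <- function(beads, scaling) {
  lam <- beads$lambda * ifelse(beads$buried, 0.7, 1) * scaling$hydro_scale
  list(sigma = beads$sigma, lambda = lam, charge = beads$charge,
       mass = beads$mass, cation = as.integer(beads$cation),
       aromatic = as.integer(beads$aromatic),
       chain = as.integer(beads$chain))
}

.scal_list <- function(scaling) {
  scaling[c("chi", "eps_ah", "cation_pi_eps", "rel_permittivity",
            "debye_length", "cutoff_hydro", "cutoff_elec")]
}

#' Build an initial direct-coexistence slab
#'
#' Places `counts` copies of each chain topology as self-avoiding random
#' walks inside a central slab occupying `slab_fraction` of the box's
#' long axis (full extent in the two short axes).  The minimum inter-bead
#' distance is 0.7 times the smallest bead diameter.  Deterministic under
#' a fixed seed.
#'
#' @param topologies A `chain_topology` or list of them.
#' @param counts Copies per topology.
#' @param box Numeric length-3 box edges, nm; the long axis should be at
#'   least about 4x the short axes for slab geometry.
#' @param params A `residue_params` table.
#' @param slab_fraction Fraction of the long axis occupied by the initial
#'   slab (default 0.25).
#' @param rng_seed Integer seed.
#' @param max_retries Placement retry budget per chain.
#' @param elastic_network Add stiff springs (k = 500 kJ/mol/nm^2) between
#'   non-bonded residue pairs of the same globular region closer than
#'   0.9 nm in the initial configuration, approximating rigid domains.
#' @param minimize_steps Capped-displacement steepest-descent steps run
#'   after placement to relax core overlaps left by the random walk
#'   (0 disables).
#' @return A `system_state` list: `positions` (N x 3, nm), `velocities`
#'   (N x 3, zero), `box`, `beads`, `bonds`, `time_ps`.
#' @export
init_slab <- function(topologies, counts, box, params,
                      slab_fraction = 0.25, rng_seed = 1,
                      max_retries = 200, elastic_network = TRUE,
                      minimize_steps = 300) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  stopifnot(length(box) == 3, all(box > 0), slab_fraction > 0,
            slab_fraction < 1)
  sys <- make_system(topologies, counts, params)
  long_axis <- which.max(box)
  lo <- box[long_axis] * (0.5 - slab_fraction / 2)
  hi <- box[long_axis] * (0.5 + slab_fraction / 2)
  dmin <- 0.7 * min(sys$beads$sigma)
  dmin2 <- dmin^2
  r0_step <- 0.38

  set.seed(rng_seed)
  pos <- matrix(NA_real_, sys$n, 3)
  placed <- 0L
  chain_lengths <- rle(sys$beads$chain)$lengths

  sample_point <- function() {
    p <- runif(3) * box
    p[long_axis] <- runif(1, lo, hi)
    p
  }
  min_image_d2 <- function(p, q) {
    d <- abs(p - q)
    d <- pmin(d, box - d)
    sum(d * d)
  }
  clashes <- function(p, upto) {
    if (upto == 0) return(FALSE)
    d <- abs(sweep(pos[seq_len(upto), , drop = FALSE], 2, p))
    d <- pmin(d, matrix(box, upto, 3, byrow = TRUE) - d)
    any(rowSums(d * d) < dmin2)
  }

  for (len in chain_lengths) {
    ok <- FALSE
    for (attempt in seq_len(max_retries)) {
      start <- sample_point()
      if (clashes(start, placed)) next
      chain_pos <- matrix(NA_real_, len, 3)
      chain_pos[1, ] <- start
      grew <- TRUE
      for (b in seq_len(len - 1)) {
        found <- FALSE
        for (d_try in seq_len(30)) {
          dir <- rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          cand <- chain_pos[b, ] + r0_step * dir
          # keep inside the slab along the long axis, wrap short axes
          if (cand[long_axis] < lo || cand[long_axis] > hi) next
          cand <- cand %% box
          if (clashes(cand, placed)) next
          if (b > 1) {
            prev <- chain_pos[seq_len(b - 1), , drop = FALSE]
            d2 <- apply(prev, 1, function(q) min_image_d2(cand, q))
            if (any(d2 < dmin2)) next
          }
          chain_pos[b + 1, ] <- cand
          found <- TRUE
          break
        }
        if (!found) { grew <- FALSE; break }
      }
      if (grew) {
        pos[placed + seq_len(len), ] <- chain_pos
        placed <- placed + len
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place chain within retry budget; ",
           "increase the box or slab_fraction (requested density too high)")
    }
  }

  bonds <- sys$bonds
  if (elastic_network && any(sys$beads$buried)) {
    en <- .elastic_network_bonds(pos, sys$beads, box)
    if (nrow(en) > 0) bonds <- rbind(bonds, en)
  }

  state <- structure(list(positions = pos,
                          velocities = matrix(0, sys$n, 3),
                          box = as.numeric(box), beads = sys$beads,
                          bonds = bonds, time_ps = 0),
                     class = "system_state")
  if (minimize_steps > 0) {
    state <- .minimize_state(state, minimize_steps)
  }
  state
}

# Steepest descent with a per-bead displacement cap: relaxes the steep
# repulsive-core overlaps a random-walk start leaves behind, so the
# integrator starts from finite forces.  Uses a purely repulsive,
# charge-free scaling (overlap removal only).
.minimize_state <- function(state, n_steps = 300, max_disp = 0.01) {
  scal <- interaction_scaling(chi = 0, hydro_scale = 1e-6,
                              cation_pi_eps = 0)
  for (s in seq_len(n_steps)) {
    ef <- cg_energy_forces(state$positions, state$box,
                           .bead_arrays(state$beads, scal),
                           as.list(state$bonds), .scal_list(scal), NULL)
    f <- ef$forces
    fmax <- sqrt(max(rowSums(f * f)))
    if (fmax < 50) break
    state$positions <- state$positions + f * (max_disp / fmax)
    state$positions <- state$positions %% matrix(state$box,
                                                 nrow(f), 3, byrow = TRUE)
  }
  state
}

# Stiff springs between residues of the same globular region within
# 0.9 nm of the initial configuration (excluding backbone neighbours).
.elastic_network_bonds <- function(pos, beads, box, radius = 0.9, k = 500) {
  out <- list()
  for (ch in unique(beads$chain[beads$buried])) {
    sel <- which(beads$chain == ch & beads$buried)
    if (length(sel) < 3) next
    for (a in seq_along(sel)) {
      for (b in seq_len(a - 1)) {
        i <- sel[a]; j <- sel[b]
        if (abs(beads$resindex[i] - beads$resindex[j]) <= 1) next
        d <- abs(pos[i, ] - pos[j, ])
        d <- pmin(d, box - d)
        r <- sqrt(sum(d^2))
        if (r < radius) {
          out[[length(out) + 1]] <-
            data.frame(i = i - 1L, j = j - 1L, r0 = r, k = k)
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
               k = numeric(0))
  } else do.call(rbind, out)
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state: ", nrow(x$positions), " beads, ",
      length(unique(x$beads$chain)), " chains, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}

#' Total energy and forces of a configuration
#'
#' Evaluates the full potential (harmonic bonds + nonbonded pair terms
#' with bonded i,i+1 pairs excluded) and its exact negative gradient
#' under the minimum-image convention.
#'
#' @param state A `system_state`.
#' @param scaling An `interaction_scaling`.
#' @param restraints Optional list with `k` (length-N spring constants,
#'   kJ/mol/nm^2; 0 disables) and `center` (N x 3 matrix).
#' @return List with `energy` (kJ/mol), per-term components (`bonded`,
#'   `hydrophobic`, `electrostatic`, `cation_pi`, `restraint`), `virial`
#'   and `forces` (N x 3, kJ/mol/nm).
#' @export
system_energy_forces <- function(state, scaling, restraints = NULL) {
  stopifnot(inherits(state, "system_state"),
            inherits(scaling, "interaction_scaling"))
  cg_energy_forces(state$positions, state$box,
                   .bead_arrays(state$beads, scaling),
                   as.list(state$bonds), .scal_list(scaling),
                   restraints)
}
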