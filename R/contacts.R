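#' Inter-chain contact frequencies
#'
#' Counts residue pairs on different chains whose minimum-image distance
#' is within `cutoff` (default 0.65 nm), averaged over trajectory frames
#' into per-frame contact probabilities.  Intra-chain pairs are
#' excluded.
#'
#' @param traj A `slab_trajectory`, or a `system_state` (treated as a
#'   single frame).
#' @param cutoff Contact distance, nm (default 0.65).
#' @param equil_fraction Fraction of initial frames discarded.
#' @return A `contact_map`: `freq` (N x N symmetric matrix of per-frame
#'   contact probabilities, zero within chains), `beads` metadata,
#'   `cutoff`, `frames`.
#' @export
interchain_contacts <- function(traj, cutoff = 0.65, equil_fraction = 0) {
  if (inherits(traj, "system_state")) {
    frames <- t(traj$positions)
    dim(frames) <- c(3, nrow(traj$positions), 1)
    traj <- list(frames = frames, box = traj$box, beads = traj$beads)
  }
  beads <- traj$beads
  if (length(unique(beads$chain)) < 2) {
    stop("contact analysis requires at least 2 chains")
  }
  n_frames <- dim(traj$frames)[3]
  first <- floor(equil_fraction * n_frames) + 1
  use <- first:n_frames
  n <- dim(traj$frames)[2]
  sub <- traj$frames[, , use, drop = FALSE]
  counts <- cg_contact_counts(as.numeric(sub), length(use), n, traj$box,
                              as.integer(beads$chain), cutoff)
  structure(list(freq = counts / length(use), beads = beads,
                 cutoff = cutoff, frames = length(use)),
            class = "contact_map")
}

#' Aggregate residue contacts into domain blocks
#'
#' Sums residue-pair contact frequencies into domain x domain blocks.
#' Domains are given as 1-based inclusive residue ranges that must tile
#' the chain; all chains are assumed to share the topology of the
#' contact map's beads.
#'
#' @param map A `contact_map`.
#' @param domains Data frame with columns `start`, `end` and optionally
#'   `name`.
#' @return Symmetric domain x domain matrix of summed frequencies.
#' @export
domain_contact_frequencies <- function(map, domains) {
  stopifnot(inherits(map, "contact_map"))
  L <- max(map$beads$resindex)
  srt <- domains[order(domains$start), , drop = FALSE]
  if (srt$start[1] != 1 || srt$end[nrow(srt)] != L ||
      (nrow(srt) > 1 && any(srt$start[-1] != srt$end[-nrow(srt)] + 1))) {
    stop("domain ranges must tile residues 1..", L)
  }
  dom_of <- integer(L)
  for (d in seq_len(nrow(domains))) {
    dom_of[domains$start[d]:domains$end[d]] <- d
  }
  bead_dom <- dom_of[map$beads$resindex]
  D <- nrow(domains)
  out <- matrix(0, D, D)
  for (a in seq_len(D)) {
    for (b in seq_len(D)) {
      out[a, b] <- sum(map$freq[bead_dom == a, bead_dom == b])
    }
  }
  nm <- if (!is.null(domains$name)) domains$name else
    sprintf("%d-%d", domains$start, domains$end)
  dimnames(out) <- list(nm, nm)
  out
}
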