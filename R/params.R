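#' Residue-level coarse-grained parameters
#'
#' A `residue_params` object is a data frame with one row per canonical
#' amino acid (one-letter code in `res`) and columns `mass` (Da), `charge`
#' (elementary charges, in {-1, 0, +1}), `sigma` (bead diameter, nm),
#' `lambda` (hydrophobicity, 0-1), plus derived logical flags `is_cation`
#' (R, K) and `is_aromatic` (F, W, Y).  The bundled default is the
#' Kapcha-Rossky-derived HPS table used by residue-resolution condensate
#' models.
#'
#' @param table_path Path to a tab-separated table with header
#'   `res mass charge sigma lambda`.  Defaults to the bundled HPS table.
#' @param his_plus Protonate histidine (+1) instead of the neutral
#'   default appropriate at pH ~7.
#' @return A validated `residue_params` data frame keyed by `res`.
#' @examples
#' p <- load_residue_params()
#' p["R", "charge"]  # +1
#' @export
load_residue_params <- function(table_path = NULL, his_plus = FALSE) {
  if (is.null(table_path)) {
    table_path <- system.file("extdata", "hps_params.tsv",
                              package = "condensr", mustWork = TRUE)
  }
  tab <- utils::read.table(table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("res", "mass", "charge", "sigma", "lambda")
  if (!all(required %in% names(tab))) {
    stop("parameter table must have columns: ", paste(required, collapse = " "))
  }
  tab$res <- toupper(tab$res)
  missing <- setdiff(AA_CODES, tab$res)
  if (length(missing) > 0) {
    stop("parameter table is missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(tab$res, AA_CODES)
  if (length(extra) > 0) {
    stop("parameter table has unknown residue code(s): ",
         paste(extra, collapse = ", "))
  }
  if (anyDuplicated(tab$res)) stop("duplicated residue rows in table")
  if (any(!is.finite(tab$mass)) || any(tab$mass <= 0)) {
    stop("residue masses must be positive and finite")
  }
  if (any(tab$lambda < 0 | tab$lambda > 1)) {
    bad <- tab$res[tab$lambda < 0 | tab$lambda > 1]
    stop("lambda outside [0, 1] for residue(s): ", paste(bad, collapse = ", "))
  }
  if (any(tab$sigma <= 0)) stop("sigma must be > 0")
  if (!all(tab$charge %in% c(-1, 0, 1))) {
    stop("charges must be in {-1, 0, +1}")
  }
  tab <- tab[match(AA_CODES, tab$res), required]
  rownames(tab) <- tab$res
  if (his_plus) tab["H", "charge"] <- 1
  tab$is_cation <- tab$res %in% c("R", "K")
  tab$is_aromatic <- tab$res %in% c("F", "W", "Y")
  class(tab) <- c("residue_params", "data.frame")
  tab
}

#' @rdname load_residue_params
#' @param params A `residue_params` object.
#' @param path Output path for the tab-separated table.
#' @export
write_residue_params <- function(params, path) {
  stopifnot(inherits(params, "residue_params"))
  utils::write.table(params[, c("res", "mass", "charge", "sigma", "lambda")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# The 20 canonical one-letter codes, fixed ordering.
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from a FASTA file
#'
#' Multi-record FASTA ingestion (via Biostrings) with strict validation:
#' sequences are uppercased and must contain only the 20 canonical
#' one-letter amino-acid codes.
#'
#' @param path FASTA file path.
#' @return Named list of sequence strings (names from FASTA headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA '", path, "': ",
                             conditionMessage(e)))
  if (length(seqs) == 0) stop("FASTA file contains no records: ", path)
  out <- toupper(as.character(seqs))
  for (i in seq_along(out)) {
    letters_i <- strsplit(out[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(letters_i %in% AA_CODES))
    if (length(bad) > 0) {
      stop("illegal residue character '", letters_i[bad[1]],
           "' at position ", bad[1], " in record '", names(out)[i], "'")
    }
  }
  as.list(out)
}

#' Build a bead-per-residue chain topology
#'
#' Consecutive residues are joined by harmonic bonds of rest length `r0`.
#' Region annotations split the chain into disordered and globular
#' stretches (1-based inclusive residue coordinates, as in sequence
#' numbering); residues inside globular regions are flagged buried and
#' their hydrophobicity is scaled down by 30% when pair energies are
#' evaluated.
#'
#' @param sequence One-letter amino-acid string.
#' @param globular_ranges List of `c(start, end)` 1-based inclusive ranges
#'   annotated as globular, or `NULL` for a fully disordered chain.
#' @param r0 Bond rest length, nm (default 0.38).
#' @param k_bond Harmonic bond constant, kJ/mol/nm^2 (default 1000).
#' @param name Chain label.
#' @return A `chain_topology` list with elements `sequence`, `length`,
#'   `bonds` (data frame `i`, `j`, `r0`, `k`; 1-based bead indices),
#'   `regions` (data frame `start`, `end`, `kind`), `buried` (logical per
#'   residue), `name`.
#' @export
build_topology <- function(sequence, globular_ranges = NULL, r0 = 0.38,
                           k_bond = 1000, name = "chain") {
  sequence <- toupper(sequence)
  letters_s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(letters_s)
  if (L < 1) stop("empty sequence")
  bad <- which(!(letters_s %in% AA_CODES))
  if (length(bad) > 0) {
    stop("illegal residue character '", letters_s[bad[1]],
         "' at position ", bad[1])
  }
  if (r0 <= 0) stop("r0 must be > 0")

  ranges <- lapply(globular_ranges, function(r) as.integer(r[1:2]))
  if (length(ranges) > 0) {
    for (r in ranges) {
      if (r[1] < 1 || r[2] > L || r[1] > r[2]) {
        stop("globular range (", r[1], ", ", r[2],
             ") outside sequence bounds [1, ", L, "]")
      }
    }
    ranges <- ranges[order(vapply(ranges, `[`, integer(1), 1))]
    for (k in seq_len(length(ranges) - 1)) {
      if (ranges[[k + 1]][1] <= ranges[[k]][2]) {
        stop("overlapping globular ranges (", ranges[[k]][1], ", ",
             ranges[[k]][2], ") and (", ranges[[k + 1]][1], ", ",
             ranges[[k + 1]][2], ")")
      }
    }
  }

  # Tile [1, L]: unannotated stretches are disordered.
  regions <- data.frame(start = integer(0), end = integer(0),
                        kind = character(0), stringsAsFactors = FALSE)
  pos <- 1L
  for (r in ranges) {
    if (pos < r[1]) {
      regions <- rbind(regions, data.frame(start = pos, end = r[1] - 1L,
                                           kind = "disordered"))
    }
    regions <- rbind(regions, data.frame(start = r[1], end = r[2],
                                         kind = "globular"))
    pos <- r[2] + 1L
  }
  if (pos <= L) {
    regions <- rbind(regions, data.frame(start = pos, end = L,
                                         kind = "disordered"))
  }

  buried <- rep(FALSE, L)
  for (k in seq_len(nrow(regions))) {
    if (regions$kind[k] == "globular") {
      buried[regions$start[k]:regions$end[k]] <- TRUE
    }
  }

  bonds <- if (L > 1) {
    data.frame(i = seq_len(L - 1), j = seq_len(L - 1) + 1L,
               r0 = r0, k = k_bond)
  } else {
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
               k = numeric(0))
  }

  structure(list(sequence = sequence, length = L, bonds = bonds,
                 regions = regions, buried = buried, name = name),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("chain_topology '", x$name, "': ", x$length, " residues, ",
      nrow(x$bonds), " bonds, ", sum(x$regions$kind == "globular"),
      " globular region(s)\n", sep = "")
  invisible(x)
}

#' Serialize / restore a chain topology as JSON
#'
#' @param topology A `chain_topology`.
#' @param path Output (or input) file path.
#' @return `read_topology` returns a `chain_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "chain_topology"))
  jsonlite::write_json(unclass(topology), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gl <- obj$regions[obj$regions$kind == "globular", , drop = FALSE]
  ranges <- if (nrow(gl) > 0) {
    lapply(seq_len(nrow(gl)), function(k) c(gl$start[k], gl$end[k]))
  } else NULL
  build_topology(obj$sequence, ranges, r0 = obj$bonds$r0[1],
                 k_bond = obj$bonds$k[1], name = obj$name)
}
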