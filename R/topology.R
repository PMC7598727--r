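#' Bead-level topology of a coarse-grained peptide system
#'
#' Describes a system of identical coarse-grained peptides in which each
#' residue carries three backbone beads (N, CA, C) and, for every
#' non-glycine residue, one side-chain bead (SC). All beads share the same
#' mass. The designated side-chain residue is the one whose side-chain
#' bead mass center represents the peptide when a fibril axis is fitted
#' (the terminal tyrosine for GNNQQNY).
#'
#' @param sequence One-letter amino-acid sequence of a single peptide,
#'   e.g. `"GNNQQNY"`. Glycine (`G`) residues carry no side-chain bead.
#' @param n_peptides Number of peptide copies in the system (N0).
#' @param side_chain_residue Index of the residue whose side-chain bead
#'   represents the peptide for axis fitting. Defaults to the last
#'   non-glycine residue; `NA` if the sequence is all glycine.
#' @param bead_mass Mass of every bead (uniform by construction). Only the
#'   ratio matters for the descriptors here, so the default of 1 is fine.
#' @return An object of class `peptide_topology`.
#' @examples
#' top <- peptide_topology("GNNQQNY", n_peptides = 20)
#' top$beads_per_peptide # 27: 21 backbone + 6 side chains (glycine has none)
#' @export
peptide_topology <- function(sequence, n_peptides,
                             side_chain_residue = NULL, bead_mass = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  stopifnot(n_peptides >= 1)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% LETTERS)) {
    stop("sequence must be one-letter amino-acid codes", call. = FALSE)
  }
  n_res <- length(res)
  has_sc <- res != "G"
  if (is.null(side_chain_residue)) {
    side_chain_residue <- if (any(has_sc)) max(which(has_sc)) else NA_integer_
  }
  if (!is.na(side_chain_residue)) {
    if (side_chain_residue < 1 || side_chain_residue > n_res) {
      stop("side_chain_residue out of range", call. = FALSE)
    }
    if (!has_sc[side_chain_residue]) {
      stop("designated side-chain residue is glycine and has no side-chain bead",
           call. = FALSE)
    }
  }
  beads <- dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
    roles <- c("N", "CA", "C", if (has_sc[i]) "SC")
    tibble::tibble(residue = i, role = roles)
  }))
  structure(
    list(
      sequence = sequence,
      residues = res,
      n_peptides = as.integer(n_peptides),
      residues_per_peptide = n_res,
      side_chain_residue = as.integer(side_chain_residue),
      bead_mass = bead_mass,
      beads = beads,
      beads_per_peptide = nrow(beads)
    ),
    class = "peptide_topology"
  )
}

#' @export
print.peptide_topology <- function(x, ...) {
  cat("<peptide_topology> ", x$sequence, "\n", sep = "")
  cat("  peptides:          ", x$n_peptides, "\n")
  cat("  residues/peptide:  ", x$residues_per_peptide, "\n")
  cat("  beads/peptide:     ", x$beads_per_peptide, "\n")
  cat("  side-chain residue:", x$side_chain_residue, "\n")
  invisible(x)
}

#' Per-bead table for all peptides of a topology
#'
#' Expands a [peptide_topology()] into one row per bead of the full
#' system, in on-disk bead order (peptide-major, then residue, then
#' N/CA/C/SC within each residue).
#'
#' @param topology A [peptide_topology()].
#' @return A tibble with columns `peptide`, `residue`, `role`.
#' @export
topology_bead_table <- function(topology) {
  stopifnot(inherits(topology, "peptide_topology"))
  dplyr::bind_rows(lapply(seq_len(topology$n_peptides), function(p) {
    dplyr::mutate(topology$beads, peptide = as.integer(p), .before = 1)
  }))
}

#' Read or write a topology configuration file
#'
#' The topology travels as a small YAML file with keys `sequence`,
#' `n_peptides`, `side_chain_residue` and `bead_mass`, rather than being
#' inferred from atom names (coarse-grained bead naming is not
#' standardized across trajectory writers).
#'
#' @param path File path.
#' @return `read_topology()` returns a [peptide_topology()];
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("sequence", "n_peptides")) {
    if (is.null(cfg[[key]])) stop("topology file missing key '", key, "'", call. = FALSE)
  }
  peptide_topology(
    sequence = cfg$sequence,
    n_peptides = cfg$n_peptides,
    side_chain_residue = cfg$side_chain_residue,
    bead_mass = if (is.null(cfg$bead_mass)) 1 else cfg$bead_mass
  )
}

#' @rdname read_topology
#' @param topology A [peptide_topology()] to serialize.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "peptide_topology"))
  yaml::write_yaml(
    list(
      sequence = topology$sequence,
      n_peptides = topology$n_peptides,
      side_chain_residue = topology$side_chain_residue,
      bead_mass = topology$bead_mass
    ),
    path
  )
  invisible(path)
}
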