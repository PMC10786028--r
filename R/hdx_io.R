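# Reading, validating and writing the tabular and sequence formats the
# pipeline touches. Coordinates are 1-based and inclusive on both ends.

CANONICAL_STATES <- c("apo", "end", "nonequilibrium")

UPTAKE_COLUMNS <- c("protein", "sequence", "start", "end", "state",
                    "replicate", "exposure_s", "uptake_da")

#' Read a single-record protein FASTA
#'
#' @param path Path to a FASTA file containing exactly one protein sequence.
#' @return Character scalar: the amino-acid sequence (1-letter codes).
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one FASTA record, found ", length(seqs))
  as.character(seqs[[1L]])
}

#' Construct a validated uptake table
#'
#' Low-level constructor used by [read_uptake_csv()] and
#' [simulate_experiment()]. Checks the key-uniqueness and state-presence
#' invariants and validates every peptide against the protein sequence.
#'
#' @param records data.frame with columns `peptide_id`, `sequence`, `start`,
#'   `end`, `state` (canonical), `replicate`, `exposure_s`, `uptake_da`.
#' @param protein_sequence Protein sequence the peptides must match.
#' @param state_map Named character vector mapping raw state labels to the
#'   canonical `apo` / `end` / `nonequilibrium`.
#' @return An object of class `hdx_uptake`.
#' @export
uptake_table <- function(records, protein_sequence,
                         state_map = setNames(CANONICAL_STATES, CANONICAL_STATES)) {
  required <- c("peptide_id", "sequence", "start", "end", "state",
                "replicate", "exposure_s", "uptake_da")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("records missing column(s): ", paste(missing, collapse = ", "))
  bad_state <- setdiff(unique(records$state), CANONICAL_STATES)
  if (length(bad_state))
    stop("non-canonical state label(s): ", paste(bad_state, collapse = ", "))

  validate_peptides(records, protein_sequence)

  key <- paste(records$peptide_id, records$state, records$replicate,
               signif(records$exposure_s, 10), sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (peptide, state, replicate, exposure) key(s), e.g. ",
         key[which(duplicated(key))[1L]])
  absent <- setdiff(CANONICAL_STATES, unique(records$state))
  if (length(absent))
    stop("no records for state(s): ", paste(absent, collapse = ", "))

  structure(list(records = records,
                 protein_sequence = protein_sequence,
                 state_map = state_map),
            class = "hdx_uptake")
}

# sequence/coordinate validation shared by the constructor and the CSV reader
validate_peptides <- function(records, protein_sequence, rows = seq_len(nrow(records))) {
  n <- nchar(protein_sequence)
  len_ok <- records$end - records$start + 1L == nchar(records$sequence)
  in_range <- records$start >= 1L & records$end <= n & records$start <= records$end
  seq_ok <- rep(FALSE, nrow(records))
  idx <- which(len_ok & in_range)
  if (length(idx))
    seq_ok[idx] <- substring(protein_sequence, records$start[idx],
                             records$end[idx]) == records$sequence[idx]
  bad <- which(!(len_ok & in_range & seq_ok))
  if (length(bad)) {
    ids <- unique(records$peptide_id[bad])
    stop("peptide/sequence validation failed for peptide_id(s) ",
         paste(utils::head(ids, 10L), collapse = ", "),
         " (rows ", paste(utils::head(rows[bad], 10L), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Read a peptide-level centroided uptake CSV
#'
#' Parses the canonical uptake dialect (one row per peptide x state x
#' replicate x exposure) and validates every row against the protein
#' sequence. Raw state labels are canonicalized through `state_map`.
#'
#' @param path CSV path with header columns `protein`, `sequence`, `start`,
#'   `end`, `state`, `replicate`, `exposure_s`, `uptake_da`.
#' @param state_map Named character vector: names are raw state values in the
#'   file, values are among `apo`, `end`, `nonequilibrium`. Must cover every
#'   state present.
#' @param sequence Protein sequence (1-letter string) the peptides must match.
#' @return An `hdx_uptake` object.
#' @export
read_uptake_csv <- function(path, state_map, sequence) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(UPTAKE_COLUMNS, names(raw))
  if (length(missing))
    stop("uptake CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  unmapped <- setdiff(unique(raw$state), names(state_map))
  if (length(unmapped))
    stop("state_map does not cover state value(s): ",
         paste(unmapped, collapse = ", "))
  bad_target <- setdiff(unname(state_map), CANONICAL_STATES)
  if (length(bad_target))
    stop("state_map maps onto non-canonical state(s): ",
         paste(bad_target, collapse = ", "))

  records <- data.frame(
    peptide_id = sprintf("p%04d_%04d", raw$start, raw$end),
    sequence   = raw$sequence,
    start      = as.integer(raw$start),
    end        = as.integer(raw$end),
    state      = unname(state_map[raw$state]),
    replicate  = as.integer(raw$replicate),
    exposure_s = as.numeric(raw$exposure_s),
    uptake_da  = as.numeric(raw$uptake_da),
    stringsAsFactors = FALSE
  )
  if (any(records$uptake_da < 0))
    stop("negative uptake_da at row(s) ",
         paste(utils::head(which(records$uptake_da < 0), 10L), collapse = ", "))
  uptake_table(records, sequence, state_map)
}

#' Write an uptake table in the canonical CSV dialect
#'
#' @param table An `hdx_uptake` object.
#' @param path Output CSV path.
#' @param protein Value for the `protein` column (a free-text name).
#' @return `path`, invisibly.
#' @export
write_uptake_csv <- function(table, path, protein = "protein") {
  r <- table$records
  out <- data.frame(protein = protein, sequence = r$sequence,
                    start = r$start, end = r$end, state = r$state,
                    replicate = r$replicate,
                    exposure_s = sprintf("%.9g", r$exposure_s),
                    uptake_da = sprintf("%.6f", r$uptake_da),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sequence coverage and per-residue redundancy of a peptide map
#'
#' @param table An `hdx_uptake` object.
#' @return List with `coverage_fraction` (covered residues / protein length)
#'   and `redundancy`, an integer vector (length = protein length) counting
#'   the peptides covering each residue.
#' @export
compute_coverage <- function(table) {
  if (!nrow(table$records)) stop("empty uptake table")
  n <- nchar(table$protein_sequence)
  peps <- unique(table$records[, c("peptide_id", "start", "end")])
  redundancy <- integer(n)
  for (i in seq_len(nrow(peps))) {
    idx <- peps$start[i]:peps$end[i]
    redundancy[idx] <- redundancy[idx] + 1L
  }
  list(coverage_fraction = sum(redundancy > 0L) / n, redundancy = redundancy)
}

#' Write residue-level profiles as TSV
#'
#' One row per residue x state x exposure; loss-free re-read with
#' [read_residue_table()].
#'
#' @param profiles `hdx_residue_profiles` data.frame from [peptide_to_residue()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(profiles, path) {
  if (is.null(profiles) || !nrow(profiles)) stop("empty residue profile set")
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("hdx_residue_profiles", "data.frame")
  out
}

#' Write kinetic fit results as TSV
#'
#' @param fits Fit table from [fit_kinetics()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  if (is.null(fits) || !nrow(fits)) stop("empty fit table")
  write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.hdx_uptake <- function(x, ...) {
  r <- x$records
  cat("neHDX-MS uptake table\n")
  cat("  protein length :", nchar(x$protein_sequence), "residues\n")
  cat("  peptides       :", length(unique(r$peptide_id)), "\n")
  cat("  states         :", paste(sort(unique(r$state)), collapse = ", "), "\n")
  cat("  exposures      :", length(unique(signif(r$exposure_s, 10))),
      sprintf("(%.3g - %.3g s)\n", min(r$exposure_s), max(r$exposure_s)))
  cat("  records        :", nrow(r), "\n")
  invisible(x)
}
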