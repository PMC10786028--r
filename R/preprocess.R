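# Normalization of centroided uptake to relative (fractional) uptake,
# replicate averaging, and peptide-to-residue averaging.

#' Normalization settings
#'
#' @param d_fraction Deuterium fraction of the labeling buffer, in (0, 1].
#' @param n_term_exclusions Number of N-terminal peptide residues excluded as
#'   fast back-exchangers (1 by convention: the first backbone amide of a
#'   peptic peptide is not observable; 2 is the common alternative).
#' @param back_exchange_factor Multiplicative deuterium-recovery factor in
#'   (0, 1]; 1 means no back-exchange correction.
#' @param length_weighted If `TRUE`, residue averaging weights each covering
#'   peptide by its exchangeable-amide count instead of equally.
#' @return A `norm_config` list.
#' @export
norm_config <- function(d_fraction = 0.9, n_term_exclusions = 1L,
                        back_exchange_factor = 1.0, length_weighted = FALSE) {
  stopifnot(d_fraction > 0, d_fraction <= 1,
            n_term_exclusions >= 0, n_term_exclusions <= 2,
            back_exchange_factor > 0, back_exchange_factor <= 1)
  structure(list(d_fraction = d_fraction,
                 n_term_exclusions = as.integer(n_term_exclusions),
                 back_exchange_factor = back_exchange_factor,
                 length_weighted = isTRUE(length_weighted)),
            class = "norm_config")
}

#' Maximum exchangeable backbone amides of a peptide
#'
#' Backbone amide count excluding prolines (which carry no amide hydrogen)
#' and the first `n_term_exclusions` N-terminal positions.
#'
#' @param peptide_sequence Character vector of 1-letter peptide sequences.
#' @param n_term_exclusions N-terminal positions to exclude (default 1).
#' @return Integer vector of exchangeable-amide counts.
#' @export
max_exchangeable_amides <- function(peptide_sequence, n_term_exclusions = 1L) {
  n_term_exclusions <- as.integer(n_term_exclusions)
  vapply(peptide_sequence, function(s) {
    len <- nchar(s)
    if (len <= n_term_exclusions)
      stop("peptide '", s, "' has no positions beyond the ",
           n_term_exclusions, " excluded N-terminal residue(s)")
    tail_seq <- substring(s, n_term_exclusions + 1L, len)
    n_pro <- lengths(regmatches(tail_seq, gregexpr("P", tail_seq, fixed = TRUE)))
    as.integer(len - n_term_exclusions - n_pro)
  }, integer(1), USE.NAMES = FALSE)
}

#' Normalize centroided uptake to relative uptake
#'
#' Relative uptake = `uptake_da / (n_exchangeable * d_fraction *
#' back_exchange_factor)`, targeting the range \[0, 1\]. Values above 1.05
#' are flagged as suspect (attribute `suspect`) but retained unclipped so
#' downstream sums are not biased.
#'
#' @param uptake_da Centroided mass increase in Daltons.
#' @param n_exchangeable Maximum exchangeable amide count (recycled).
#' @param config A [norm_config()].
#' @return Numeric vector of relative uptake with logical attribute `suspect`.
#' @export
relative_uptake <- function(uptake_da, n_exchangeable, config = norm_config()) {
  out <- rep(NA_real_, length(uptake_da))
  n_exchangeable <- rep_len(n_exchangeable, length(uptake_da))
  zero <- n_exchangeable == 0L
  if (any(zero))
    warning(sum(zero), " value(s) with zero exchangeable amides excluded (NA)")
  denom <- n_exchangeable * config$d_fraction * config$back_exchange_factor
  out[!zero] <- uptake_da[!zero] / denom[!zero]
  suspect <- !is.na(out) & out > 1.05
  if (any(suspect))
    warning(sum(suspect), " normalized value(s) > 1.05 flagged as suspect")
  attr(out, "suspect") <- suspect
  out
}

#' Replicate-averaged normalized peptide time courses
#'
#' Normalizes every record with [relative_uptake()] and averages replicates
#' per (peptide, state, exposure). With a single replicate the SD is reported
#' as `NA`, never 0.
#'
#' @param table An `hdx_uptake` object.
#' @param config A [norm_config()].
#' @return `hdx_peptide_means` data.frame: `peptide_id`, `sequence`, `start`,
#'   `end`, `state`, `exposure_s`, `rel_uptake`, `sd_rel_uptake`, `n_rep`,
#'   `n_exchangeable`, `suspect`.
#' @export
average_replicates <- function(table, config = norm_config()) {
  r <- table$records
  pep_info <- unique(r[, c("peptide_id", "sequence", "start", "end")])
  n_ex <- max_exchangeable_amides(pep_info$sequence, config$n_term_exclusions)
  names(n_ex) <- pep_info$peptide_id
  excluded <- names(n_ex)[n_ex == 0L]
  if (length(excluded)) {
    warning("peptide(s) with zero exchangeable amides excluded: ",
            paste(excluded, collapse = ", "))
    r <- r[!(r$peptide_id %in% excluded), , drop = FALSE]
  }
  rel <- suppressWarnings(
    relative_uptake(r$uptake_da, n_ex[r$peptide_id], config))

  key <- interaction(r$peptide_id, r$state, signif(r$exposure_s, 10), drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(
    peptide_id = r$peptide_id[first], sequence = r$sequence[first],
    start = r$start[first], end = r$end[first], state = r$state[first],
    exposure_s = r$exposure_s[first], stringsAsFactors = FALSE)
  grp <- split(as.numeric(rel), key)[levels(key)]
  ord <- match(key[first], levels(key))
  out$rel_uptake <- vapply(grp, mean, numeric(1))[ord]
  out$sd_rel_uptake <- vapply(grp, function(v)
    if (length(v) > 1L) sd(v) else NA_real_, numeric(1))[ord]
  out$n_rep <- vapply(grp, length, integer(1))[ord]
  out$n_exchangeable <- as.integer(n_ex[out$peptide_id])
  out$suspect <- out$rel_uptake > 1.05
  out <- out[order(out$peptide_id, out$state, out$exposure_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hdx_peptide_means", "data.frame")
  out
}

# Snap exposure values to a canonical grid: values within rel_tol of each
# other collapse onto one grid point; returns the canonical value per input.
match_time_grid <- function(exposure_s, rel_tol = 1e-6) {
  u <- sort(unique(exposure_s))
  grid <- u[1L]
  for (v in u[-1L])
    if (abs(v - grid[length(grid)]) > rel_tol * max(abs(v), .Machine$double.eps))
      grid <- c(grid, v)
  grid[vapply(exposure_s, function(v) which.min(abs(grid - v)), integer(1))]
}

#' Average peptide-level time courses to residue resolution
#'
#' For each residue and state, averages the normalized uptake of all covering
#' peptides at each shared time point. A peptide does not contribute to a
#' residue that falls within its first `n_term_exclusions` positions, and
#' proline residues (no backbone amide) are absent from the output entirely.
#' The propagated SD is the root-mean-square of the contributing peptide SDs
#' divided by the square root of the number of contributing peptides.
#'
#' @param pep_means `hdx_peptide_means` from [average_replicates()].
#' @param protein_sequence Protein sequence (for proline positions).
#' @param config A [norm_config()]; `n_term_exclusions` and `length_weighted`
#'   are used here.
#' @return `hdx_residue_profiles` data.frame: `residue`, `state`,
#'   `exposure_s`, `rel_uptake`, `sd_rel_uptake`, `n_peptides`.
#' @export
peptide_to_residue <- function(pep_means, protein_sequence, config = norm_config()) {
  excl <- config$n_term_exclusions
  pep_means$exposure_s <- match_time_grid(pep_means$exposure_s)
  aa <- strsplit(protein_sequence, "")[[1L]]

  peps <- unique(pep_means[, c("peptide_id", "start", "end", "n_exchangeable")])
  # residue -> covering peptide ids (respecting exclusions and prolines)
  cover <- vector("list", length(aa))
  for (i in seq_len(nrow(peps))) {
    lo <- peps$start[i] + excl
    if (lo > peps$end[i]) next
    for (r in lo:peps$end[i])
      if (aa[r] != "P") cover[[r]] <- c(cover[[r]], peps$peptide_id[i])
  }

  idx <- split(seq_len(nrow(pep_means)),
               list(pep_means$state, pep_means$exposure_s), drop = TRUE)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    block <- pep_means[idx[[j]], , drop = FALSE]
    vals <- setNames(block$rel_uptake, block$peptide_id)
    sds  <- setNames(block$sd_rel_uptake, block$peptide_id)
    wts  <- setNames(as.numeric(block$n_exchangeable), block$peptide_id)
    res_rows <- lapply(which(lengths(cover) > 0L), function(r) {
      ids <- intersect(cover[[r]], block$peptide_id)
      if (!length(ids)) return(NULL)
      v <- vals[ids]
      w <- if (config$length_weighted) wts[ids] else rep(1, length(ids))
      s <- sds[ids]
      s_ok <- s[!is.na(s)]
      data.frame(residue = r, state = block$state[1L],
                 exposure_s = block$exposure_s[1L],
                 rel_uptake = sum(w * v) / sum(w),
                 sd_rel_uptake = if (length(s_ok))
                   sqrt(mean(s_ok^2)) / sqrt(length(ids)) else NA_real_,
                 n_peptides = length(ids), stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, res_rows)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) stop("no residues covered after exclusions")
  out <- out[order(out$residue, out$state, out$exposure_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hdx_residue_profiles", "data.frame")
  out
}
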