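# Mechanistic forward simulator of millisecond HDX labeling during a
# ligand-induced three-state conformational relaxation (apo -> transient ->
# end, sequential first order). Exchange follows the EX2 limit: the
# instantaneous exchange rate of a residue is the population-weighted sum of
# its per-state rates k_int / P_state, so centroided (single-envelope) uptake
# is the correct measurement model. Ligand mixing occurs one dead time before
# the earliest exposure, so nonequilibrium occupancies at the first time point
# already reflect dead_time_s of relaxation.

#' Log-spaced labeling schedule
#'
#' @param n_points Number of exposures (>= 2).
#' @param t_min,t_max First and last exposure in seconds (0 < t_min < t_max).
#' @return Strictly increasing vector of `n_points` log-spaced times with the
#'   end points exactly `t_min` and `t_max`.
#' @export
make_schedule <- function(n_points = 31, t_min = 0.05, t_max = 300) {
  stopifnot(n_points >= 2, t_min > 0, t_min < t_max)
  out <- exp(seq(log(t_min), log(t_max), length.out = n_points))
  out[1L] <- t_min; out[n_points] <- t_max
  out
}

#' Occupancies of the sequential three-state relaxation
#'
#' Closed form for A -> B -> C with first-order rates `k1` (apo -> transient)
#' and `k2` (transient -> end), starting from pure apo at `t = 0`. The equal
#' rate case uses its analytic limit `f_trans = k1 t exp(-k1 t)`.
#'
#' @param t Time(s) since ligand mixing, seconds.
#' @param k1,k2 Conformational rates in 1/s.
#' @return Data.frame with columns `f_apo`, `f_trans`, `f_end`; rows sum to 1.
#' @export
population_kinetics <- function(t, k1, k2) {
  stopifnot(all(t >= 0), k1 > 0, k2 > 0)
  f_apo <- exp(-k1 * t)
  f_trans <- if (abs(k1 - k2) < 1e-9 * k1) k1 * t * exp(-k1 * t)
             else k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  data.frame(f_apo = f_apo, f_trans = f_trans,
             f_end = 1 - f_apo - f_trans)
}

# Cumulative occupancies int_0^t f_state(tau) dtau (closed form).
occupancy_cumulative <- function(t, k1, k2) {
  F_apo <- (1 - exp(-k1 * t)) / k1
  F_trans <- if (abs(k1 - k2) < 1e-9 * k1)
    (1 - (1 + k1 * t) * exp(-k1 * t)) / k1
  else
    k1 / (k2 - k1) * ((1 - exp(-k1 * t)) / k1 - (1 - exp(-k2 * t)) / k2)
  list(apo = F_apo, trans = F_trans, end = t - F_apo - F_trans)
}

#' Kinetic behavior classes of the default simulation
#'
#' Each class is a signature of observed exchange rates (1/s) in the apo,
#' transient and end conformations; residue-level protection factors are
#' derived as `P_state = k_int / k_state`, so residues in one region share
#' correlated kinetics while `k_int` still varies between residues.
#' `instant = TRUE` classes complete their local structural change within the
#' experimental dead time (ligand-contact sites and early on-pathway
#' rearrangements), so their nonequilibrium curve coincides with the end
#' state and they sit exactly on the y = 0 axis of the sum-difference plane.
#' `expected_archetype` is the archetype each class produces by construction.
#'
#' @return Data.frame: `class`, `k_apo`, `k_trans`, `k_end`, `instant`,
#'   `expected_archetype`.
#' @export
behavior_classes <- function() {
  data.frame(
    class  = c("unchanged", "interpolating", "on_pathway_protected",
               "on_pathway_deprotected", "transient_deprotection",
               "transient_protection", "binding_site"),
    k_apo   = c(1e-3, 1e-4, 8e-2, 1e-4, 2e-4, 3e-1, 2e-2),
    k_trans = c(1e-3, 2e-3, 1e-4, 8e-2, 8e-2, 1e-4, 4e-3),
    k_end   = c(1e-3, 3e-2, 1e-4, 8e-2, 2e-4, 3e-1, 4e-3),
    instant = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    expected_archetype = c("unchanged", "interpolating deprotection",
                           "on-pathway protection", "on-pathway deprotection",
                           "transient deprotection", "transient protection",
                           "on-pathway protection"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults mirror the nonequilibrium activation experiment: 31 log-spaced
#' exposures from the 50 ms dead time to 300 s, 3 replicates, 7 contiguous
#' regions (one per behavior class) over a 120-residue protein, conformational
#' rates k1 = 0.5, k2 = 0.2 1/s, replicate noise 0.01 relative-uptake units.
#' The `"inhibition"` preset switches to the 20-point schedule.
#'
#' @param protein_length Number of residues.
#' @param regions Data.frame (`class`, `start`, `end`) assigning behavior
#'   classes to residue ranges; `NULL` for the default 7 equal blocks in
#'   [behavior_classes()] order.
#' @param n_points,t_min,t_max Labeling schedule ([make_schedule()]).
#' @param k1,k2 Conformational relaxation rates, 1/s.
#' @param dead_time_s Experimental dead time; must equal `t_min`.
#' @param replicates Replicates per state and exposure.
#' @param noise_sd Replicate noise SD in relative-uptake units (scaled by each
#'   peptide's exchangeable-amide count on the Dalton scale).
#' @param d_fraction Deuterium fraction of the labeling buffer.
#' @param pep_len_min,pep_len_max Peptide length range of the synthetic map.
#' @param min_overlap Minimum overlap between consecutive peptides.
#' @param rate_jitter Lognormal SD of the per-residue factor shared by all
#'   three state rates (residue-to-residue variation within a region).
#' @param state_jitter Lognormal SD of the small state-specific rate factor.
#' @param preset `NULL`, `"activation"` (31 points) or `"inhibition"`
#'   (20 points).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(protein_length = 120L, regions = NULL,
                       n_points = 31L, t_min = 0.05, t_max = 300,
                       k1 = 0.5, k2 = 0.2, dead_time_s = 0.05,
                       replicates = 3L, noise_sd = 0.01, d_fraction = 0.9,
                       pep_len_min = 6L, pep_len_max = 18L, min_overlap = 3L,
                       rate_jitter = 0.15, state_jitter = 0.05,
                       preset = NULL, seed = 0L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("activation", "inhibition"))
    n_points <- if (preset == "activation") 31L else 20L
  }
  stopifnot(t_min == dead_time_s, protein_length >= 14L,
            pep_len_min >= 2L, pep_len_max >= pep_len_min,
            min_overlap >= 1L, min_overlap < pep_len_min)
  if (is.null(regions)) {
    cls <- behavior_classes()$class
    bounds <- floor(seq(0, protein_length, length.out = length(cls) + 1L))
    regions <- data.frame(class = cls, start = bounds[-length(bounds)] + 1L,
                          end = bounds[-1L], stringsAsFactors = FALSE)
  }
  structure(list(protein_length = as.integer(protein_length), regions = regions,
                 n_points = as.integer(n_points), t_min = t_min, t_max = t_max,
                 k1 = k1, k2 = k2, dead_time_s = dead_time_s,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 d_fraction = d_fraction, pep_len_min = as.integer(pep_len_min),
                 pep_len_max = as.integer(pep_len_max),
                 min_overlap = as.integer(min_overlap),
                 rate_jitter = rate_jitter, state_jitter = state_jitter,
                 preset = preset, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw the per-residue ground truth of a simulation
#'
#' Generates a random protein sequence (prolines at ~5%), assigns each residue
#' its region's behavior class, jitters the class rate signature (one shared
#' lognormal factor per residue plus a small state-specific factor), draws
#' `k_int` log-uniformly, and converts observed rates to protection factors
#' `P_state = k_int / k_state` (all >= 1 because `k_int` is drawn above the
#' fastest state rate of the residue).
#'
#' @param config A [sim_config()].
#' @return Data.frame (class `hdx_ground_truth`): `residue`, `aa`,
#'   `behavior_class`, `k_int`, `P_apo`, `P_trans`, `P_end`, `instant`.
#' @export
make_ground_truth <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$protein_length
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  wts <- rep(1, 20); wts[aa20 == "P"] <- 1  # ~5% proline
  sequence <- sample(aa20, n, replace = TRUE, prob = wts / sum(wts))

  cls_tab <- behavior_classes()
  cls <- rep(NA_character_, n)
  for (i in seq_len(nrow(config$regions)))
    cls[config$regions$start[i]:config$regions$end[i]] <- config$regions$class[i]
  if (anyNA(cls)) stop("region map does not cover every residue")
  ci <- match(cls, cls_tab$class)

  shared <- exp(rnorm(n, 0, config$rate_jitter))
  st <- matrix(exp(rnorm(3L * n, 0, config$state_jitter)), ncol = 3L)
  k_apo   <- cls_tab$k_apo[ci]   * shared * st[, 1L]
  k_trans <- cls_tab$k_trans[ci] * shared * st[, 2L]
  k_end   <- cls_tab$k_end[ci]   * shared * st[, 3L]

  lo <- pmax(1e-2, k_apo, k_trans, k_end)
  k_int <- exp(runif(n, log(lo), log(10)))

  out <- data.frame(residue = seq_len(n), aa = sequence, behavior_class = cls,
                    k_int = k_int, P_apo = k_int / k_apo,
                    P_trans = k_int / k_trans, P_end = k_int / k_end,
                    instant = cls_tab$instant[ci], stringsAsFactors = FALSE)
  attr(out, "sequence") <- paste(sequence, collapse = "")
  class(out) <- c("hdx_ground_truth", "data.frame")
  out
}

#' True relative uptake of one residue
#'
#' EX2 exchange during the conformational relaxation: the cumulative hazard at
#' exposure `t` is `k_int` times the occupancy-weighted time each conformation
#' contributes at its protection level, and `D(t) = 1 - exp(-hazard)`.
#' Equilibrium modes hold occupancy fixed on one state. In nonequilibrium
#' mode the population has already relaxed for `dead_time_s` when labeling
#' starts; `instant = TRUE` residues (ligand binding sites) are fully switched
#' to the end conformation from the first instant of labeling.
#'
#' @param res One ground-truth row (list or 1-row data.frame with `k_int`,
#'   `P_apo`, `P_trans`, `P_end` and optional `instant`).
#' @param times Exposure times in seconds.
#' @param mode `"apo"`, `"end"` or `"nonequilibrium"`.
#' @param k1,k2 Conformational rates, 1/s.
#' @param dead_time_s Dead time between ligand mixing and the start of
#'   labeling (seconds).
#' @return Relative uptake per time, monotone non-decreasing in \[0, 1).
#' @export
simulate_residue_uptake <- function(res, times, mode = c("nonequilibrium", "apo", "end"),
                                    k1 = 0.5, k2 = 0.2, dead_time_s = 0.05) {
  mode <- match.arg(mode)
  k_int <- res$k_int
  hazard <- switch(mode,
    apo = k_int / res$P_apo * times,
    end = k_int / res$P_end * times,
    nonequilibrium = {
      if (isTRUE(res$instant)) {
        k_int / res$P_end * times
      } else {
        F1 <- occupancy_cumulative(times + dead_time_s, k1, k2)
        F0 <- occupancy_cumulative(dead_time_s, k1, k2)
        k_int * ((F1$apo - F0$apo) / res$P_apo +
                 (F1$trans - F0$trans) / res$P_trans +
                 (F1$end - F0$end) / res$P_end)
      }
    })
  1 - exp(-hazard)
}

# Random overlapping peptide map. Peptides are tiled within each behavior
# region (they do not straddle region boundaries) so that every residue's
# generating class is identifiable from peptide-level data; real peptic maps
# do cross structural boundaries, which blurs residue-level ground truth near
# edges -- a realism the fixture deliberately trades away.
make_peptide_map <- function(config, n = config$protein_length) {
  regions <- config$regions
  starts <- integer(0); ends <- integer(0)
  for (ri in seq_len(nrow(regions))) {
    lo <- regions$start[ri]; hi <- regions$end[ri]
    reg_len <- hi - lo + 1L
    pmax_len <- min(config$pep_len_max, reg_len)
    pmin_len <- min(config$pep_len_min, pmax_len)
    start <- lo
    repeat {
      len <- sample(pmin_len:pmax_len, 1L)
      end <- min(start + len - 1L, hi)
      if (end - start + 1L < pmin_len) {  # short tail: right-anchor
        start <- max(lo, hi - len + 1L); end <- hi
      }
      starts <- c(starts, start); ends <- c(ends, end)
      if (end >= hi) break
      max_ov <- max(config$min_overlap, len - 4L)
      overlap <- if (max_ov > config$min_overlap)
        sample(config$min_overlap:max_ov, 1L) else config$min_overlap
      start <- min(start + (len - overlap), end + 1L)
    }
  }
  data.frame(peptide_id = sprintf("p%04d_%04d", starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Simulate a full nonequilibrium HDX-MS experiment
#'
#' Draws the ground truth, tiles an overlapping peptide map over the sequence,
#' computes each peptide's centroided uptake in Daltons as `d_fraction` times
#' the sum of its exchangeable residues' true uptake, and adds i.i.d. Gaussian
#' replicate noise with SD `noise_sd * n_exchangeable` (truncated at 0: a mass
#' increase cannot be negative). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: writes `uptake.csv` (canonical dialect),
#'   `protein.fasta` and `ground_truth.json` there.
#' @return List with `table` (`hdx_uptake`), `ground_truth`, `peptide_map`,
#'   `schedule` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), out_dir = NULL) {
  gt <- make_ground_truth(config)  # seeds with config$seed
  sequence <- attr(gt, "sequence")
  schedule <- make_schedule(config$n_points, config$t_min, config$t_max)

  set.seed(config$seed + 1L)
  pmap <- make_peptide_map(config)
  cov_res <- unique(unlist(mapply(seq, pmap$start, pmap$end, SIMPLIFY = FALSE)))
  if (length(cov_res) < config$protein_length)
    warning("peptide map covers ", length(cov_res), "/", config$protein_length,
            " residues")

  states <- c("apo", "end", "nonequilibrium")
  # true residue uptake curves, residue x time, per state
  true_uptake <- lapply(setNames(states, states), function(st)
    t(vapply(seq_len(nrow(gt)), function(i)
      simulate_residue_uptake(gt[i, ], schedule, st, config$k1, config$k2,
                              config$dead_time_s),
      numeric(length(schedule)))))

  set.seed(config$seed + 2L)
  aa <- strsplit(sequence, "")[[1L]]
  recs <- vector("list", nrow(pmap) * length(states))
  idx <- 0L
  for (i in seq_len(nrow(pmap))) {
    pos <- (pmap$start[i] + 1L):pmap$end[i]       # first residue unobservable
    pos <- pos[aa[pos] != "P"]
    n_ex <- length(pos)
    pep_seq <- substring(sequence, pmap$start[i], pmap$end[i])
    for (st in states) {
      true_da <- config$d_fraction *
        (if (n_ex) colSums(true_uptake[[st]][pos, , drop = FALSE]) else
           rep(0, length(schedule)))
      for (rep_i in seq_len(config$replicates)) {
        noise <- if (config$noise_sd > 0)
          rnorm(length(schedule), 0, config$noise_sd * max(n_ex, 1L)) else 0
        idx <- idx + 1L
        recs[[idx]] <- data.frame(
          peptide_id = pmap$peptide_id[i], sequence = pep_seq,
          start = pmap$start[i], end = pmap$end[i], state = st,
          replicate = rep_i, exposure_s = schedule,
          uptake_da = pmax(0, true_da + noise), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  table <- uptake_table(records, sequence)

  result <- list(table = table, ground_truth = gt, peptide_map = pmap,
                 schedule = schedule, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_uptake_csv(table, file.path(out_dir, "uptake.csv"))
    writeLines(c(">synthetic_protein", sequence),
               file.path(out_dir, "protein.fasta"))
    gt_json <- list(config = unclass(config)[setdiff(names(config), "regions")],
                    regions = config$regions, residues = as.data.frame(gt))
    jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
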