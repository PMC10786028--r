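test_that("max exchangeable amides follows the counting rule", {
  expect_equal(max_exchangeable_amides("PEPTIDE", 1), 5L)  # 7 - 1 - P at pos 3
  expect_equal(max_exchangeable_amides("AAAA", 1), 3L)
  expect_equal(max_exchangeable_amides("APPA", 1), 1L)
  expect_error(max_exchangeable_amides("A", 1), "excluded")

  # brute-force position scan over the default synthetic peptide map
  sim <- small_sim()
  peps <- unique(sim$table$records[, c("sequence", "start", "end")])
  brute <- vapply(peps$sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(seq_along(chars) > 1 & chars != "P")
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(max_exchangeable_amides(peps$sequence, 1), as.integer(brute))
})

test_that("relative uptake normalizes, flags suspects, and is linear", {
  cfg <- norm_config(d_fraction = 0.9, back_exchange_factor = 1)
  expect_equal(as.numeric(relative_uptake(0, 5, cfg)), 0)
  expect_equal(as.numeric(relative_uptake(5 * 0.9, 5, cfg)), 1.0)
  # linearity and scale invariance
  u <- as.numeric(relative_uptake(c(1, 2, 4), 8, cfg))
  expect_equal(u[2] / u[1], 2); expect_equal(u[3] / u[1], 4)
  expect_equal(as.numeric(relative_uptake(2 * 1.8, 2 * 8, cfg)),
               as.numeric(relative_uptake(1.8, 8, cfg)))
  # suspect flag above 1.05, retained unclipped
  expect_warning(v <- relative_uptake(10, 5, cfg), "suspect")
  expect_gt(as.numeric(v), 1.05)
  expect_true(attr(v, "suspect"))
  # zero exchangeable amides: NA with warning, not a division error
  expect_warning(z <- relative_uptake(1, 0, cfg), "zero exchangeable")
  expect_true(is.na(as.numeric(z)))
})

test_that("noiseless simulated peptide recovers its plateau after normalization", {
  sim <- simulate_experiment(sim_config(protein_length = 70L, n_points = 10L,
                                        replicates = 1L, noise_sd = 0,
                                        t_max = 1e5, dead_time_s = 0.05,
                                        seed = 3))
  cfg <- norm_config(d_fraction = sim$config$d_fraction)
  pm <- average_replicates(sim$table, cfg)
  # peptides whose every contributing residue exchanges with k_apo >= 1e-3/s
  # must be fully deuterated (normalized uptake 1) by t = 1e5 s in apo state
  gt <- sim$ground_truth
  fast <- gt$residue[gt$k_int / gt$P_apo >= 1e-3]
  pmap <- sim$peptide_map
  all_fast <- vapply(seq_len(nrow(pmap)), function(i)
    all((pmap$start[i] + 1):pmap$end[i] %in% fast), logical(1))
  cand <- pm[pm$state == "apo" & pm$exposure_s == max(pm$exposure_s) &
               pm$peptide_id %in% pmap$peptide_id[all_fast], ]
  expect_gt(nrow(cand), 0)
  expect_true(all(abs(cand$rel_uptake - 1) < 1e-6))
})

test_that("replicate averaging gives mean and sample SD, NA for single replicate", {
  protein <- "MKTAYIAKQRMKTA"
  mk <- function(rep, uptake, state = "apo") data.frame(
    peptide_id = "p1", sequence = "KTAYIA", start = 2, end = 7, state = state,
    replicate = rep, exposure_s = 1, uptake_da = uptake)
  recs <- rbind(mk(1, 0.2), mk(2, 0.2), mk(3, 0.2),
                mk(1, 0.1, "end"), mk(2, 0.3, "end"),
                mk(1, 0.5, "nonequilibrium"))
  tab <- uptake_table(recs, protein)
  cfg <- norm_config(d_fraction = 1)
  out <- average_replicates(tab, cfg)
  n_ex <- max_exchangeable_amides("KTAYIA", 1)
  apo <- out[out$state == "apo", ]
  expect_equal(apo$rel_uptake, 0.2 / n_ex)
  expect_equal(apo$sd_rel_uptake, 0)
  en <- out[out$state == "end", ]
  expect_equal(en$rel_uptake, 0.2 / n_ex)
  expect_equal(en$sd_rel_uptake, sd(c(0.1, 0.3)) / n_ex, tolerance = 1e-12)
  expect_equal(round(en$sd_rel_uptake * n_ex, 4), 0.1414)
  ne <- out[out$state == "nonequilibrium", ]
  expect_true(is.na(ne$sd_rel_uptake))
  expect_equal(ne$n_rep, 1L)
})

test_that("replicate noise is recovered in the pooled SD", {
  sim <- simulate_experiment(sim_config(protein_length = 70L, n_points = 8L,
                                        replicates = 3L, noise_sd = 0.01,
                                        seed = 7))
  cfg <- norm_config(d_fraction = sim$config$d_fraction)
  pm <- suppressWarnings(average_replicates(sim$table, cfg))
  # noise sd on the Dalton scale is noise_sd * n_ex, so normalized it is
  # noise_sd / d_fraction ~ 0.011 (truncation of negative masses at 0 Da
  # shrinks it to ~0.0065 for unexchanged peptides). Pool each peptide's SD
  # estimates across its time points to beat triplet-SD sampling noise.
  pooled <- tapply(pm$sd_rel_uptake, paste(pm$peptide_id, pm$state),
                   function(s) sqrt(mean(s^2, na.rm = TRUE)))
  expect_gt(mean(pooled >= 0.005 & pooled <= 0.02), 0.95)
})

test_that("residue averaging is bounded by covering peptides and excludes prolines", {
  # one peptide covering residues 5-10: residues 6-10 inherit it exactly
  protein <- "AAAAKTAYIAAAAA"
  mk <- function(state) data.frame(
    peptide_id = "p1", sequence = "KTAYIA", start = 5, end = 10, state = state,
    replicate = 1, exposure_s = 1, uptake_da = 1.0)
  tab <- uptake_table(do.call(rbind, lapply(c("apo", "end", "nonequilibrium"), mk)),
                      protein)
  cfg <- norm_config(d_fraction = 1)
  pm <- average_replicates(tab, cfg)
  rp <- peptide_to_residue(pm, protein, cfg)
  expect_setequal(unique(rp$residue), 6:10)
  expect_true(all(abs(rp$rel_uptake - 1 / 5) < 1e-12))

  # two overlapping peptides: covered residue gets the plain mean
  protein2 <- "AAKTAYIAKQAA"
  mk2 <- function(id, start, end, seq, u, state) data.frame(
    peptide_id = id, sequence = seq, start = start, end = end, state = state,
    replicate = 1, exposure_s = 1, uptake_da = u)
  n1 <- max_exchangeable_amides("KTAYIA", 1)   # peptide 3-8
  n2 <- max_exchangeable_amides("YIAKQA", 1)   # peptide 6-11
  recs <- do.call(rbind, lapply(c("apo", "end", "nonequilibrium"), function(s)
    rbind(mk2("a", 3, 8, "KTAYIA", 0.2 * n1, s),
          mk2("b", 6, 11, "YIAKQA", 0.4 * n2, s))))
  rp2 <- peptide_to_residue(average_replicates(uptake_table(recs, protein2), cfg),
                            protein2, cfg)
  r8 <- rp2[rp2$residue == 8 & rp2$state == "apo", ]  # covered by both
  expect_equal(r8$rel_uptake, 0.3)
  expect_equal(r8$n_peptides, 2L)

  # exhaustive bounding check + proline absence on synthetic data
  sim <- small_sim()
  cfg2 <- norm_config(d_fraction = sim$config$d_fraction)
  pms <- suppressWarnings(average_replicates(sim$table, cfg2))
  rps <- peptide_to_residue(pms, sim$table$protein_sequence, cfg2)
  aa <- strsplit(sim$table$protein_sequence, "")[[1]]
  expect_false(any(aa[unique(rps$residue)] == "P"))
  pmap <- sim$peptide_map
  key <- paste(pms$peptide_id, pms$state, signif(pms$exposure_s, 10))
  val <- setNames(pms$rel_uptake, key)
  withr::local_seed(11)
  for (i in sample(nrow(rps), 200)) {
    r <- rps$residue[i]
    ids <- pmap$peptide_id[pmap$start + 1 <= r & pmap$end >= r]
    vs <- val[paste(ids, rps$state[i], signif(rps$exposure_s[i], 10))]
    vs <- vs[!is.na(vs)]
    expect_gte(rps$rel_uptake[i], min(vs) - 1e-12)
    expect_lte(rps$rel_uptake[i], max(vs) + 1e-12)
  }
})
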