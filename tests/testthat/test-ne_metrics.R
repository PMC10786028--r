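# residue profiles built by hand: a convenient constructor
make_profiles <- function(residues, times, f_apo, f_end, f_ne, sd = 0.01) {
  rows <- expand.grid(residue = residues, exposure_s = times)
  mk <- function(state, f) data.frame(residue = rows$residue, state = state,
                                      exposure_s = rows$exposure_s,
                                      rel_uptake = f(rows$residue, rows$exposure_s),
                                      sd_rel_uptake = sd, n_peptides = 1L)
  out <- rbind(mk("apo", f_apo), mk("end", f_end), mk("nonequilibrium", f_ne))
  class(out) <- c("hdx_residue_profiles", "data.frame")
  out
}

test_that("sum difference: identical states give the origin; ne = end sits on y = 0", {
  times <- make_schedule(8, 0.1, 100)
  f <- function(r, t) 1 - exp(-0.01 * t)
  same <- make_profiles(1:4, times, f, f, f)
  co <- sum_difference(same)
  expect_equal(co$x, rep(0, 4))
  expect_equal(co$y, rep(0, 4))

  g <- function(r, t) 1 - exp(-0.1 * t)  # end more exchanged than apo
  done <- make_profiles(1:4, times, f, g, g)  # two-state completion: ne = end
  co2 <- sum_difference(done)
  expect_equal(co2$y, rep(0, 4))
  expect_true(all(co2$x > 0))
})

test_that("sum difference is antisymmetric under swapping reference states", {
  times <- make_schedule(10, 0.05, 300)
  prof <- make_profiles(1:6, times,
                        function(r, t) 1 - exp(-0.001 * r * t),
                        function(r, t) 1 - exp(-0.01 * t),
                        function(r, t) 0.5 * (1 - exp(-0.05 * t)))
  co <- sum_difference(prof)
  swapped <- prof
  swapped$state <- c(apo = "end", end = "apo",
                     nonequilibrium = "nonequilibrium")[prof$state]
  co2 <- sum_difference(swapped)
  expect_equal(co2$x, co$y)
  expect_equal(co2$y, co$x)
})

test_that("transient deprotection integrates to x > 0 and y > 0 (quadrature oracle)", {
  res <- list(k_int = 1, P_apo = 5000, P_trans = 12.5, P_end = 5000,
              instant = FALSE)
  times <- make_schedule(31, 0.05, 300)
  k1 <- 0.5; k2 <- 0.2
  ne <- simulate_residue_uptake(res, times, "nonequilibrium", k1, k2, 0.05)
  ap <- simulate_residue_uptake(res, times, "apo", k1, k2, 0.05)
  en <- simulate_residue_uptake(res, times, "end", k1, k2, 0.05)
  # independent quadrature of the same physics
  ne_oracle <- oracle_ne_uptake(res$k_int, res$P_apo, res$P_trans, res$P_end,
                                times, k1, k2, 0.05)
  expect_equal(ne, ne_oracle, tolerance = 1e-8)
  expect_gt(sum(ne - ap), 0)
  expect_gt(sum(ne - en), 0)

  prof <- make_profiles(1, times,
                        function(r, t) ap[match(t, times)],
                        function(r, t) en[match(t, times)],
                        function(r, t) ne[match(t, times)])
  co <- sum_difference(prof)
  expect_equal(co$x, sum(ne - ap), tolerance = 1e-12)
  expect_equal(co$y, sum(ne - en), tolerance = 1e-12)
})

test_that("archetype classification partitions the plane into exactly 9 labels", {
  grid <- expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1))
  co <- data.frame(residue = seq_len(nrow(grid)), x = grid$x, y = grid$y,
                   sigma_x = 0.1, sigma_y = 0.1, n_times = 10L)
  out <- classify_archetype(co, z_threshold = 2)
  expect_equal(length(unique(out$archetype)), 9L)
  expect_equal(sort(unique(out$archetype)), sort(as.vector(archetype_names())))
  expect_equal(out$archetype[grid$x == 0 & grid$y == 0], "unchanged")
  expect_equal(out$archetype[grid$x == 1 & grid$y == 1],
               "transient deprotection")
  expect_equal(out$archetype[grid$x == -1 & grid$y == -1],
               "transient protection")
  # zero band scales with sigma: |x| <= z*sigma is "zero"
  co2 <- data.frame(residue = 1, x = 0.15, y = -0.5, sigma_x = 0.1,
                    sigma_y = 0.1, n_times = 10L)
  expect_equal(classify_archetype(co2, 2)$archetype, "lagging deprotection")
  expect_equal(classify_archetype(co2, 1)$archetype, "interpolating deprotection")
  # missing sigma: flagged, classified by sign alone
  co3 <- data.frame(residue = 1, x = 1e-9, y = 0, sigma_x = NA_real_,
                    sigma_y = NA_real_, n_times = 1L)
  out3 <- classify_archetype(co3)
  expect_true(out3$sigma_missing)
  expect_equal(out3$archetype, "on-pathway deprotection")
})

test_that("every finite coordinate maps to exactly one archetype (property)", {
  withr::local_seed(5)
  co <- data.frame(residue = 1:500, x = rnorm(500), y = rnorm(500),
                   sigma_x = abs(rnorm(500, 0, 0.2)),
                   sigma_y = abs(rnorm(500, 0, 0.2)), n_times = 5L)
  out <- classify_archetype(co)
  expect_false(anyNA(out$archetype))
  expect_true(all(out$archetype %in% as.vector(archetype_names())))
})

test_that("k-means separates well-separated clouds and is deterministic", {
  withr::local_seed(3)
  cloud <- rbind(cbind(rnorm(30, 0, 0.1), rnorm(30, 0, 0.1)),
                 cbind(rnorm(30, 5, 0.1), rnorm(30, 5, 0.1)))
  co <- data.frame(residue = 1:60, x = cloud[, 1], y = cloud[, 2],
                   sigma_x = 0.1, sigma_y = 0.1, n_times = 10L)
  cl <- kmeans_cluster(co, k = 2, seed = 1)
  truth <- rep(1:2, each = 30)
  agreement <- max(mean(cl$assignments == truth),
                   mean(cl$assignments == 3 - truth))
  expect_equal(agreement, 1.0)
  # determinism under identical seed
  cl2 <- kmeans_cluster(co, k = 2, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)
  expect_identical(cl$centroids, cl2$centroids)
  # dendrogram over centroids has k leaves, Newick exports
  cl7 <- kmeans_cluster(co, k = 5, seed = 1)
  expect_equal(length(cl7$linkage$order), 5L)
  nwk <- cluster_newick(cl7)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), paste0("c", 1:5))
  # errors and degenerate input
  expect_error(kmeans_cluster(co, k = 61), "exceeds")
  flat <- co; flat$x <- 1; flat$y <- 1
  expect_warning(cl1 <- kmeans_cluster(flat, k = 3), "identical")
  expect_equal(cl1$k, 1L)
})

test_that("saturation check passes saturated reporters and fails unsaturated", {
  protein <- "MKTAYIAKQRMKTA"
  mk <- function(state, rep, u) data.frame(
    peptide_id = "p1", sequence = "KTAYIA", start = 2, end = 7, state = state,
    replicate = rep, exposure_s = 0.05, uptake_da = u)
  mk2 <- function(...) {  # second exposure so the table is realistic
    d <- mk(...); d$exposure_s <- 10; d
  }
  cfg <- norm_config(d_fraction = 1)
  # identical replicate sets in both states -> pass
  recs <- rbind(mk("nonequilibrium", 1, 0.50), mk("nonequilibrium", 2, 0.52),
                mk("end", 1, 0.50), mk("end", 2, 0.52),
                mk("apo", 1, 0.10), mk2("apo", 1, 0.2),
                mk2("nonequilibrium", 1, 0.9), mk2("end", 1, 0.9))
  out <- saturation_check(uptake_table(recs, protein), "p1", config = cfg)
  expect_true(out$pass)
  expect_true(attr(out, "overall_pass"))

  # strongly different means -> fail
  recs2 <- rbind(mk("nonequilibrium", 1, 0.50), mk("nonequilibrium", 2, 0.52),
                 mk("end", 1, 2.50), mk("end", 2, 2.55),
                 mk("apo", 1, 0.10))
  out2 <- saturation_check(uptake_table(recs2, protein), "p1", config = cfg)
  expect_false(out2$pass)

  # absent reporter fails with reason "unmeasured"
  out3 <- saturation_check(uptake_table(recs, protein), c("p1", "nope"),
                           config = cfg)
  expect_false(out3$pass[out3$peptide_id == "nope"])
  expect_match(out3$reason[out3$peptide_id == "nope"], "unmeasured")
})

test_that("dead-time saturation verdict follows the binding kinetics", {
  # reporter peptide whose site switches within the dead time -> pass;
  # a slow-switching site (still mostly apo at 50 ms) -> fail
  times <- make_schedule(6, 0.05, 100)
  protein <- strrep("A", 12)
  build <- function(k_on) {
    f_sw <- population_kinetics(0.05, k_on, k_on * 2)$f_end +
      population_kinetics(0.05, k_on, k_on * 2)$f_trans
    mk <- function(state, rep) {
      u_end <- 5 * (1 - exp(-0.5 * times))       # protected site: end state
      u_apo <- 5 * (1 - exp(-5 * times))
      u <- switch(state, end = u_end, apo = u_apo,
                  nonequilibrium = f_sw * u_end + (1 - f_sw) * u_apo)
      data.frame(peptide_id = "rep1", sequence = "AAAAAA", start = 1, end = 6,
                 state = state, replicate = rep, exposure_s = times,
                 uptake_da = u + 0.005 * rep)
    }
    uptake_table(rbind(mk("apo", 1), mk("apo", 2), mk("end", 1), mk("end", 2),
                       mk("nonequilibrium", 1), mk("nonequilibrium", 2)),
                 protein)
  }
  cfg <- norm_config(d_fraction = 1)
  fast <- saturation_check(build(200), "rep1", config = cfg)   # ~10 ms switch
  expect_true(fast$pass)
  slow <- saturation_check(build(1.4), "rep1", config = cfg)   # ~500 ms switch
  expect_false(slow$pass)
})
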