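# Independent oracles and small fixtures, deliberately implemented by routes
# different from the package internals.

# brute-force coverage: enumerate every residue index covered by any interval
oracle_coverage <- function(starts, ends, n) {
  covered <- unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE)))
  length(intersect(covered, seq_len(n))) / n
}

# numerical-quadrature uptake oracle: integrate the instantaneous EX2 rate
# k(tau) = k_int * sum_s f_s(tau + dead) / P_s with stats::integrate
oracle_ne_uptake <- function(k_int, P_apo, P_trans, P_end, times,
                             k1, k2, dead_time) {
  rate <- function(tau) {
    f <- population_kinetics(tau + dead_time, k1, k2)
    k_int * (f$f_apo / P_apo + f$f_trans / P_trans + f$f_end / P_end)
  }
  vapply(times, function(t) {
    L <- stats::integrate(rate, 0, t, rel.tol = 1e-10)$value
    1 - exp(-L)
  }, numeric(1))
}

# quaternion-based superposition RMSD (Horn 1987), independent of Kabsch/bio3d
oracle_super_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  R <- matrix(c(
    q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2), 3, 3, byrow = TRUE)
  Br <- B %*% t(R)
  sqrt(mean(rowSums((A - Br)^2)))
}

# minimal valid uptake CSV on a toy protein
write_toy_csv <- function(path, protein = "MKTAYIAKQR",
                          states = c(A = "apo", B = "end", C = "nonequilibrium")) {
  rows <- expand.grid(state = names(states), exposure_s = c(0.1, 1, 10),
                      replicate = 1:2, stringsAsFactors = FALSE)
  df <- data.frame(protein = "toy", sequence = "KTAYIA", start = 2, end = 7,
                   state = rows$state, replicate = rows$replicate,
                   exposure_s = rows$exposure_s,
                   uptake_da = 0.5 + 0.01 * rows$replicate)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  states
}

# small deterministic simulation used by several suites (fast defaults)
small_sim <- function(seed = 1, ...) {
  simulate_experiment(sim_config(protein_length = 70L, n_points = 12L,
                                 replicates = 2L, seed = seed, ...))
}

# rigid-motion helper: rotate+translate an n x 3 coordinate matrix
rigid_move <- function(X, angle = 0.7, axis = c(0, 0, 1), shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(X %*% t(R), 2, -shift)
}
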