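# Per-residue 2D sum-difference coordinates, the nine transient-kinetics
# archetypes, k-means clustering with a centroid dendrogram, and the
# dead-time ligand-saturation check.

#' Per-residue sum-difference coordinates
#'
#' For each residue present in all three states on a shared time grid,
#' computes `x = sum_t (ne - apo)` and `y = sum_t (ne - end)` over the
#' identical time-point set, with uncertainties propagated in quadrature from
#' the per-time SDs. A residue missing any state is skipped (and reported via
#' the `skipped` attribute). Swapping the two reference states swaps x and y.
#'
#' @param profiles `hdx_residue_profiles` containing the states `apo`, `end`
#'   and `nonequilibrium`.
#' @param statistic `"sum"` (default) or `"mean"` per time point; the mean
#'   guards against unequal grid sizes between experiments.
#' @return `hdx_coords` data.frame: `residue`, `x`, `y`, `sigma_x`, `sigma_y`,
#'   `n_times`.
#' @export
sum_difference <- function(profiles, statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  profiles$exposure_s <- match_time_grid(profiles$exposure_s)
  by_res <- split(profiles, profiles$residue)
  rows <- lapply(by_res, function(p) {
    ne <- p[p$state == "nonequilibrium", ]
    ap <- p[p$state == "apo", ]
    en <- p[p$state == "end", ]
    if (!nrow(ne) || !nrow(ap) || !nrow(en)) return(NULL)
    shared <- Reduce(intersect, list(ne$exposure_s, ap$exposure_s, en$exposure_s))
    if (!length(shared)) return(NULL)
    shared <- sort(shared)
    ne <- ne[match(shared, ne$exposure_s), ]
    ap <- ap[match(shared, ap$exposure_s), ]
    en <- en[match(shared, en$exposure_s), ]
    agg <- if (statistic == "sum") sum else mean
    sd0 <- function(s) ifelse(is.na(s), 0, s)
    scale <- if (statistic == "sum") 1 else 1 / length(shared)
    data.frame(
      residue = p$residue[1L],
      x = agg(ne$rel_uptake - ap$rel_uptake),
      y = agg(ne$rel_uptake - en$rel_uptake),
      sigma_x = scale * sqrt(sum(sd0(ne$sd_rel_uptake)^2 + sd0(ap$sd_rel_uptake)^2)),
      sigma_y = scale * sqrt(sum(sd0(ne$sd_rel_uptake)^2 + sd0(en$sd_rel_uptake)^2)),
      n_times = length(shared))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no residue has a shared time grid across all three states")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  attr(out, "skipped") <- as.integer(names(by_res))[!keep]
  class(out) <- c("hdx_coords", "data.frame")
  out
}

#' The nine archetype labels of nonequilibrium structural kinetics
#'
#' Each axis of the sum-difference plane is classified as negative, zero or
#' positive, giving 3 x 3 = 9 archetypes. Zero means within the statistical
#' zero-band `|value| <= z * sigma`.
#'
#' @return Character matrix (rows = x class, cols = y class) of the 9 labels.
#' @export
archetype_names <- function() {
  m <- matrix(c(
    # y = -1 (ne < end)           y = 0 (ne ~ end)          y = +1 (ne > end)
    "transient protection",       "on-pathway protection",  "interpolating protection",   # x = -1
    "lagging deprotection",       "unchanged",              "lagging protection",         # x =  0
    "interpolating deprotection", "on-pathway deprotection","transient deprotection"      # x = +1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(x = c("-1", "0", "1"), y = c("-1", "0", "1")))
  m
}

#' Classify residues into the nine transient-kinetics archetypes
#'
#' An axis value is "zero" when `|value| <= z_threshold * sigma`; otherwise its
#' sign decides the class. `(0, 0)` is "unchanged"; `x > 0, y > 0` is
#' "transient deprotection" (more exchange than either equilibrium state);
#' `x != 0, y = 0` are on-pathway completions lying on the y = 0 axis.
#' Missing sigmas are treated as 0 (pure sign classification) and flagged.
#'
#' @param coords `hdx_coords` from [sum_difference()].
#' @param z_threshold Width of the zero band in sigma units (default 2).
#' @return `coords` with added columns `x_class`, `y_class` (-1/0/1),
#'   `archetype`, and `sigma_missing`.
#' @export
classify_archetype <- function(coords, z_threshold = 2) {
  sig_missing <- !is.finite(coords$sigma_x) | !is.finite(coords$sigma_y)
  sx <- ifelse(is.finite(coords$sigma_x), coords$sigma_x, 0)
  sy <- ifelse(is.finite(coords$sigma_y), coords$sigma_y, 0)
  xc <- ifelse(abs(coords$x) <= z_threshold * sx, 0L, as.integer(sign(coords$x)))
  yc <- ifelse(abs(coords$y) <= z_threshold * sy, 0L, as.integer(sign(coords$y)))
  nm <- archetype_names()
  coords$x_class <- xc
  coords$y_class <- yc
  coords$archetype <- nm[cbind(as.character(xc), as.character(yc))]
  coords$sigma_missing <- sig_missing
  coords
}

#' k-means clustering of sum-difference coordinates with centroid dendrogram
#'
#' k-means on the raw (unscaled) `(x, y)` coordinates — both axes share units,
#' so standardization would distort the geometry — followed by average-linkage
#' hierarchical clustering of the k centroids (Euclidean distance) to give the
#' cluster dendrogram. `k = "auto"` selects k over `k_range` by maximum mean
#' silhouette width.
#'
#' @param coords `hdx_coords` (finite `x`, `y` required).
#' @param k Cluster count (default 7), or `"auto"`.
#' @param seed RNG seed; recorded in the result.
#' @param nstart Random restarts for each k-means run (default 25).
#' @param k_range Candidate k values for `"auto"`.
#' @return `hdx_clusters`: list with `k`, `assignments` (integer vector named
#'   by residue), `centroids`, `linkage` (an `hclust` over centroids, `NULL`
#'   for k = 1), `inertia`, `seed`, and `silhouette` (mean widths per
#'   candidate k when `k = "auto"`).
#' @export
kmeans_cluster <- function(coords, k = 7, seed = 0, nstart = 25, k_range = 2:12) {
  xy <- as.matrix(coords[, c("x", "y")])
  rownames(xy) <- coords$residue
  if (!all(is.finite(xy))) stop("non-finite coordinates; filter before clustering")
  n <- nrow(xy)

  if (nrow(unique(xy)) == 1L) {
    warning("all coordinates identical; returning a single cluster")
    return(structure(list(k = 1L,
                          assignments = setNames(rep(1L, n), rownames(xy)),
                          centroids = xy[1, , drop = FALSE], linkage = NULL,
                          inertia = 0, seed = seed, silhouette = NULL),
                     class = "hdx_clusters"))
  }

  run_k <- function(kk) {
    set.seed(seed)
    kmeans(xy, centers = kk, nstart = nstart, iter.max = 100)
  }

  sil <- NULL
  if (identical(k, "auto")) {
    cand <- k_range[k_range < n]
    d <- dist(xy)
    sil <- vapply(cand, function(kk) {
      km <- run_k(kk)
      mean(cluster::silhouette(km$cluster, d)[, 3])
    }, numeric(1))
    names(sil) <- cand
    k <- cand[which.max(sil)]
  }
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " exceeds the number of residues (", n, ")")

  km <- run_k(k)
  linkage <- if (k >= 2L) {
    hc <- hclust(dist(km$centers), method = "average")
    hc$labels <- paste0("c", seq_len(k))
    hc
  } else NULL
  structure(list(k = k, assignments = setNames(km$cluster, rownames(xy)),
                 centroids = km$centers, linkage = linkage,
                 inertia = km$tot.withinss, seed = seed, silhouette = sil),
            class = "hdx_clusters")
}

#' Newick string for the cluster-centroid dendrogram
#'
#' Leaf names are the cluster labels (`c1` ... `ck`); branch lengths are the
#' average-linkage merge heights (Euclidean distance, arbitrary units).
#'
#' @param clusters `hdx_clusters` from [kmeans_cluster()] (k >= 2).
#' @return Newick string.
#' @export
cluster_newick <- function(clusters) {
  if (is.null(clusters$linkage)) stop("no dendrogram for k < 2")
  ape::write.tree(ape::as.phylo(clusters$linkage))
}

#' @export
print.hdx_clusters <- function(x, ...) {
  cat("k-means clustering of sum-difference coordinates\n")
  cat("  k =", x$k, " seed =", x$seed,
      " within-cluster SS =", format(x$inertia, digits = 4), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Ligand-saturation check within the labeling dead time
#'
#' For reporter peptides at the ligand binding sites, compares normalized
#' uptake at the earliest exposure between the nonequilibrium and end states
#' (Welch two-sample t-test). If binding saturates within the dead time, the
#' two are indistinguishable: a reporter passes iff `p > alpha` AND the
#' absolute mean difference is below `max_diff` relative-uptake units (the
#' effect-size gate guards against meaningless p-values at tiny n).
#'
#' @param table `hdx_uptake`.
#' @param reporter_peptides Character vector of peptide ids to test.
#' @param alpha Significance level (default 0.05).
#' @param max_diff Effect-size gate in relative-uptake units (default 0.05).
#' @param config [norm_config()] used for normalization.
#' @return `hdx_saturation` data.frame: `peptide_id`, `p_value`, `mean_diff`,
#'   `pass`, `reason`; overall verdict in attribute `overall_pass`.
#' @export
saturation_check <- function(table, reporter_peptides, alpha = 0.05,
                             max_diff = 0.05, config = norm_config()) {
  r <- table$records
  pep_info <- unique(r[, c("peptide_id", "sequence")])
  n_ex <- setNames(max_exchangeable_amides(pep_info$sequence,
                                           config$n_term_exclusions),
                   pep_info$peptide_id)
  rows <- lapply(reporter_peptides, function(pid) {
    fail <- function(reason) data.frame(peptide_id = pid, p_value = NA_real_,
                                        mean_diff = NA_real_, pass = FALSE,
                                        reason = reason, stringsAsFactors = FALSE)
    sub <- r[r$peptide_id == pid & r$state %in% c("nonequilibrium", "end"), ]
    if (!nrow(sub) || length(unique(sub$state)) < 2L) return(fail("unmeasured"))
    t0 <- min(sub$exposure_s)
    sub <- sub[abs(sub$exposure_s - t0) <= 1e-6 * t0, ]
    u_ne <- suppressWarnings(relative_uptake(
      sub$uptake_da[sub$state == "nonequilibrium"], n_ex[pid], config))
    u_end <- suppressWarnings(relative_uptake(
      sub$uptake_da[sub$state == "end"], n_ex[pid], config))
    if (length(u_ne) < 2L || length(u_end) < 2L)
      return(fail("fewer than 2 replicates at the earliest exposure"))
    diff_mean <- mean(u_ne) - mean(u_end)
    p <- if (sd(u_ne) == 0 && sd(u_end) == 0) {
      if (abs(diff_mean) < 1e-12) 1 else 0  # degenerate: identical replicates
    } else t.test(as.numeric(u_ne), as.numeric(u_end))$p.value
    pass <- p > alpha && abs(diff_mean) < max_diff
    data.frame(peptide_id = pid, p_value = p, mean_diff = diff_mean,
               pass = pass,
               reason = if (pass) "saturated within dead time"
                        else "nonequilibrium differs from end state at dead time",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_pass") <- all(out$pass)
  class(out) <- c("hdx_saturation", "data.frame")
  out
}
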