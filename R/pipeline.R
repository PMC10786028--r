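# End-to-end pipeline: input (CSV/FASTA or simulation) -> normalization and
# replicate averaging -> residue averaging -> kinetic fits -> sum-difference
# coordinates -> archetypes -> clustering -> output bundle with manifest.

#' Pipeline configuration
#'
#' Either point `uptake_csv`/`fasta` at measured data (with a `state_map`), or
#' set `simulate = TRUE` to run on synthetic data from [simulate_experiment()].
#'
#' @param uptake_csv Path to the canonical uptake CSV (ignored if simulating).
#' @param fasta Path to the single-record protein FASTA (ignored if simulating).
#' @param state_map Named character vector canonicalizing raw state labels.
#' @param simulate If `TRUE`, generate the input with [simulate_experiment()].
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param normalization A [norm_config()].
#' @param k Cluster count or `"auto"`.
#' @param cluster_seed Seed for k-means restarts (recorded in outputs).
#' @param z_threshold Zero-band width for [classify_archetype()].
#' @param sum_statistic `"sum"` or `"mean"` for [sum_difference()].
#' @param reporters Optional peptide ids for [saturation_check()].
#' @param alpha Significance level of the saturation check.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(uptake_csv = NULL, fasta = NULL, state_map = NULL,
                            simulate = is.null(uptake_csv), sim = sim_config(),
                            normalization = norm_config(), k = 7,
                            cluster_seed = 0L, z_threshold = 2,
                            sum_statistic = "sum", reporters = NULL,
                            alpha = 0.05) {
  structure(list(uptake_csv = uptake_csv, fasta = fasta, state_map = state_map,
                 simulate = simulate, sim = sim, normalization = normalization,
                 k = k, cluster_seed = as.integer(cluster_seed),
                 z_threshold = z_threshold, sum_statistic = sum_statistic,
                 reporters = reporters, alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `sim` and `normalization` are nested maps passed to [sim_config()] and
#' [norm_config()].
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("sim", "normalization")))]
  if (!is.null(y$state_map)) args$state_map <- unlist(y$state_map)
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$normalization))
    args$normalization <- do.call(norm_config, y$normalization)
  do.call(pipeline_config, args)
}

#' Run the full neHDX-MS analysis pipeline
#'
#' Executes every stage and writes the result bundle to `out_dir`:
#' `residues.tsv`, `fits.tsv`, `coordinates.tsv`, `clusters.json`,
#' `dendrogram.nwk`, `run.log`, and `manifest.json` listing every output with
#' its MD5 content hash. Deterministic given the configuration and seeds. A
#' stage failure aborts with the stage name; files written so far are listed
#' in the error's `partial_manifest` attribute.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible `nehdx_run` list: `table`, `peptide_means`, `residues`,
#'   `fits`, `coordinates`, `clusters`, `saturation` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial_manifest") <- written
      stop(err)
    })
  }

  sim_out <- NULL
  table <- stage("input", {
    if (isTRUE(config$simulate)) {
      log_msg("simulating experiment (seed ", config$sim$seed, ")")
      sim_out <- simulate_experiment(config$sim)
      sim_out$table
    } else {
      log_msg("reading ", config$uptake_csv)
      read_uptake_csv(config$uptake_csv, config$state_map,
                      read_protein_fasta(config$fasta))
    }
  })
  log_msg("input: ", nrow(table$records), " records, ",
          length(unique(table$records$peptide_id)), " peptides")
  cov <- compute_coverage(table)
  log_msg(sprintf("coverage: %.1f%% of the sequence",
                  100 * cov$coverage_fraction))

  pep_means <- stage("preprocess",
                     suppressWarnings(average_replicates(table, config$normalization)))
  residues <- stage("residue_average",
                    peptide_to_residue(pep_means, table$protein_sequence,
                                       config$normalization))
  log_msg("residue profiles: ", length(unique(residues$residue)), " residues")
  write_residue_table(residues, file.path(out_dir, "residues.tsv"))
  written <- c(written, "residues.tsv")

  fits <- stage("kinetics", fit_kinetics(pep_means))
  log_msg("kinetic fits: ", nrow(fits), " (", sum(fits$slow), " slow, k_obs < 1e-5/s)")
  write_fit_table(fits, file.path(out_dir, "fits.tsv"))
  written <- c(written, "fits.tsv")

  coords <- stage("sum_difference", {
    co <- sum_difference(residues, statistic = config$sum_statistic)
    classify_archetype(co, config$z_threshold)
  })
  log_msg("coordinates: ", nrow(coords), " residues; archetypes: ",
          paste(names(sort(table(coords$archetype), decreasing = TRUE)),
                collapse = ", "))
  write.table(coords, file.path(out_dir, "coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  written <- c(written, "coordinates.tsv")

  clusters <- stage("clustering",
                    kmeans_cluster(coords, k = config$k, seed = config$cluster_seed))
  log_msg("clustering: k = ", clusters$k, ", seed = ", clusters$seed)
  cl_json <- list(k = clusters$k, seed = clusters$seed,
                  inertia = clusters$inertia,
                  silhouette = as.list(clusters$silhouette),
                  centroids = unname(apply(clusters$centroids, 1, as.list)),
                  assignments = as.list(clusters$assignments))
  jsonlite::write_json(cl_json, file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, "clusters.json")
  if (!is.null(clusters$linkage)) {
    writeLines(cluster_newick(clusters), file.path(out_dir, "dendrogram.nwk"))
    written <- c(written, "dendrogram.nwk")
  }

  saturation <- NULL
  if (!is.null(config$reporters)) {
    saturation <- stage("saturation",
                        saturation_check(table, config$reporters, config$alpha,
                                         config = config$normalization))
    log_msg("saturation check: ",
            if (attr(saturation, "overall_pass")) "PASS" else "FAIL")
    write.table(saturation, file.path(out_dir, "saturation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    written <- c(written, "saturation.tsv")
  }

  writeLines(log_lines, log_path)

  manifest <- list(
    seeds = list(simulation = if (isTRUE(config$simulate)) config$sim$seed else NULL,
                 clustering = config$cluster_seed),
    k = clusters$k,
    files = lapply(setNames(written, written), function(f)
      list(md5 = unname(md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(table = table, sim = sim_out,
                           peptide_means = pep_means, residues = residues,
                           fits = fits, coordinates = coords,
                           clusters = clusters, saturation = saturation,
                           manifest = manifest, out_dir = out_dir),
                      class = "nehdx_run"))
}

#' @export
print.nehdx_run <- function(x, ...) {
  cat("neHDX-MS pipeline run ->", x$out_dir, "\n")
  cat("  residues:", length(unique(x$residues$residue)),
      " coordinates:", nrow(x$coordinates),
      " clusters: k =", x$clusters$k, "\n")
  invisible(x)
}
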