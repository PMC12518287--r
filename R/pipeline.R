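# End-to-end orchestration: validated configuration, staged execution,
# TSV reports and a run log. The package's functions (and this driver)
# are the command surface; each stage is equally callable on its own.

#' Build or read a pipeline configuration
#'
#' A configuration is a named list; [validate_config()] fills defaults
#' and checks ranges before anything is computed. Recognized fields:
#' `spot_table`, `sample_sheet` (paths; omit both to simulate),
#' `proteins` (FASTA path, optional), `promoters` (FASTA path, optional),
#' `motif_library` (TSV path, optional; defaults to the bundled set),
#' `test` (`moderated`/`kruskal`/`mixed`), `adjustment` (`BH`/`Holm`),
#' `alpha`, `delta`, `random_factor`, `seed`, `output_dir`, and for
#' simulation `n_spots_per_group`, `organ`, `effect_log2`, `noise_sd`.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A named list of configuration values.
#' @export
validate_config <- function(config) {
  defaults <- list(test = "moderated", adjustment = "BH", alpha = 0.05,
                   delta = 0.05, random_factor = "replicate", seed = 1L,
                   output_dir = "digeflow_out", n_spots_per_group = 20L,
                   organ = "shoot", effect_log2 = 2, noise_sd = 0.3)
  for (nm in names(defaults))
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!config$test %in% c("moderated", "kruskal", "mixed"))
    stop("unknown test: ", config$test)
  if (!config$adjustment %in% c("BH", "Holm"))
    stop("unknown adjustment: ", config$adjustment)
  if (config$delta < 0) stop("delta must be non-negative")
  for (f in c("spot_table", "sample_sheet", "proteins", "promoters",
              "motif_library"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configured path does not exist: ", f, " = ", config[[f]])
  config
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Stages, in order: load or simulate the spot table; log2 transform and
#' quantile normalize; per-spot significance test with adjustment;
#' significant-spot selection; k-means and hierarchical clustering of
#' samples and spots with concordance scores; trajectory classification;
#' optional protein physicochemistry (when a protein FASTA is
#' configured); optional promoter scanning and family summaries (when a
#' promoter FASTA is configured). Every stage writes a TSV report into
#' `output_dir`; parameters and seeds are recorded in `run.log`.
#'
#' @param config Configuration list (see [read_config()]).
#' @param dry_run Validate the configuration and inputs without
#'   computing (default `FALSE`).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  config <- validate_config(config)
  if (dry_run) {
    message("configuration valid; dry run requested, nothing computed")
    return(invisible(config$output_dir))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "digeflow ", as.character(utils::packageVersion("digeflow")),
           "; R ", getRversion())
  log_line(con, "parameters: test=", config$test, " adjustment=",
           config$adjustment, " alpha=", config$alpha, " delta=",
           config$delta, " seed=", config$seed)
  stage <- function(name, expr) {
    log_line(con, "stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      log_line(con, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(con, "stage ", name, " done")
    res
  }
  outpath <- function(f) file.path(config$output_dir, f)
  wtsv <- function(df, f) utils::write.table(
    df, outpath(f), sep = "\t", quote = FALSE, row.names = FALSE)

  raw <- stage("load", {
    if (!is.null(config$spot_table)) {
      read_spot_table(config$spot_table, config$sample_sheet)
    } else {
      sim <- generate_spot_table(
        config$n_spots_per_group, make_design(config$organ),
        trajectory_specs(effect_log2 = config$effect_log2,
                         noise_sd = config$noise_sd),
        seed = config$seed)
      wtsv(data.frame(spot_id = names(sim$groups), group = sim$groups),
           "simulated_truth.tsv")
      sim$table
    }
  })
  norm <- stage("normalize", quantile_normalize(log2_and_average(raw)))
  wtsv(data.frame(spot_id = norm$spot_ids, norm$matrix,
                  check.names = FALSE), "normalized_intensities.tsv")

  tests <- stage("test", spot_tests(norm, method = config$test,
                                    adjustment = config$adjustment,
                                    random_factor = config$random_factor))
  sig <- stage("select", select_significant(tests, alpha = config$alpha))
  tests$significant <- tests$spot_id %in% sig
  wtsv(tests, "spot_tests.tsv")

  clust <- stage("cluster", {
    X <- t(norm$matrix)  # samples in rows
    ksel <- select_k_elbow(X, k_max = min(6L, nrow(X) - 1L),
                           seed = config$seed)
    km <- kmeans_cluster(X, k = as.integer(ksel), seed = config$seed)
    D <- stats::dist(X)
    khc <- select_k_silhouette(D, k_max = min(8L, nrow(X) - 1L))
    hc <- hier_cluster(D, k = as.integer(khc))
    wtsv(data.frame(sample_id = km$item_ids, kmeans = km$labels,
                    hierarchical = hc$labels), "sample_clusters.tsv")
    list(kmeans = km, hier = hc)
  })
  conc <- stage("concordance", {
    data.frame(
      mode = c("simpson", "jaccard"),
      S = c(partition_concordance(clust$kmeans, clust$hier, "simpson")$S,
            partition_concordance(clust$kmeans, clust$hier, "jaccard")$S))
  })
  wtsv(conc, "clustering_concordance.tsv")

  traj <- stage("trajectory", call_trajectories(norm, delta = config$delta))
  wtsv(traj, "trajectories.tsv")

  if (!is.null(config$proteins)) {
    stage("proteochem", {
      rec <- dedup_sequences(read_proteins(config$proteins))
      props <- data.frame(
        accession = rec$accession, organ = rec$organ,
        length = nchar(rec$sequence),
        mw_kda = vapply(rec$sequence, compute_mw, numeric(1)) / 1000,
        pI = vapply(rec$sequence, compute_pI, numeric(1)))
      wtsv(props, "protein_properties.tsv")
      props
    })
  }
  if (!is.null(config$promoters)) {
    stage("promoters", {
      aa <- Biostrings::readDNAStringSet(config$promoters)
      prom <- data.frame(
        gene_id = sub("\\s.*$", "", names(aa)),
        sequence = as.character(aa), strand = "+",
        length = Biostrings::width(aa),
        truncated = Biostrings::width(aa) < 500L)
      lib <- if (!is.null(config$motif_library))
        read_motif_library(config$motif_library) else default_motif_library()
      hits <- scan_motifs(prom, lib)
      wtsv(hits, "motif_hits.tsv")
      wtsv(family_summary(hits, prom$gene_id, families = lib$family),
           "family_summary.tsv")
      wtsv(positional_hit_profile(hits, region_length = max(prom$length)),
           "hit_positions.tsv")
      wtsv(data.frame(gene_id = prom$gene_id,
                      at_content = at_content(prom$sequence)),
           "promoter_at_content.tsv")
      invisible(NULL)
    })
  }
  log_line(con, "pipeline complete; outputs in ", config$output_dir)
  invisible(config$output_dir)
}
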