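#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either `matrix_path` +
#' `annotation_path` (real-format inputs) or `simulation` (a
#' [SimulationConfig-class]) must be supplied.
#'
#' @param matrix_path,annotation_path expression/annotation TSVs (see
#'   [readExpressionTSV()]), or `NULL` when simulating.
#' @param simulation a [SimulationConfig-class], or `NULL`.
#' @param mapping_path optional probeset-to-gene mapping TSV; when present
#'   the validation stage runs.
#' @param gene_sets_path optional GMT of benchmark gene lists.
#' @param universe_path optional one-symbol-per-line universe file; defaults
#'   to all genes in the mapping.
#' @param min_group_size paired-subset threshold (default 20).
#' @param alpha model-stage significance level (default 0.01).
#' @param B number of permutations (default 200 for desk-scale runs; set
#'   10000 for compendium-scale inference).
#' @param lambda \eqn{\pi_0} tuning parameter (default 0.5).
#' @param top_n probeset-reduction series for the map stage; `Inf` means
#'   all probesets.
#' @param seed master seed; each stage derives its own child seed from it,
#'   so stages can be rerun in isolation.
#' @param output_dir artifact directory (created if needed).
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(matrix_path = NULL, annotation_path = NULL,
                           simulation = NULL, mapping_path = NULL,
                           gene_sets_path = NULL, universe_path = NULL,
                           min_group_size = 20L, alpha = 0.01, B = 200L,
                           lambda = 0.5, top_n = Inf, seed = 1L,
                           output_dir = tempfile("oncomap_run_")) {
  if (is.null(simulation) && (is.null(matrix_path) || is.null(annotation_path)))
    stop("supply either matrix_path + annotation_path or a simulation config")
  if (!is.null(simulation)) stopifnot(is(simulation, "SimulationConfig"))
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(lambda, "lambda", lower = 1e-12, upper = 1 - 1e-12)
  B <- assert_count(B, "B")
  min_group_size <- assert_count(min_group_size, "min_group_size")
  cfg <- list(matrix_path = matrix_path, annotation_path = annotation_path,
              simulation = simulation, mapping_path = mapping_path,
              gene_sets_path = gene_sets_path, universe_path = universe_path,
              min_group_size = min_group_size, alpha = alpha, B = B,
              lambda = lambda, top_n = top_n, seed = as.integer(seed),
              output_dir = output_dir)
  class(cfg) <- "PipelineConfig"
  cfg
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  df <- as.data.frame(df)
  if (!is.null(rownames(df)) &&
      !identical(rownames(df), as.character(seq_len(nrow(df))))) {
    df <- cbind(id = rownames(df), df)
    rownames(df) <- NULL
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full meta-analysis pipeline
#'
#' Executes, in order: data loading (or simulation), paired-subset
#' construction, the group-level map stage (similarity, group means,
#' clustering, PCA, optionally on a most-variable-probeset series), the
#' between-group-variance stage, the mixed-model stage, the permutation /
#' FDR stage, and (when a gene mapping is configured) the gene-collapsing
#' and list-validation stage. Every stage writes its TSV artifacts under
#' `config$output_dir`, and a machine-readable `run_summary.json` collects
#' the headline counts. Reruns with an identical config are bit-identical.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, the run summary as a list (also written as JSON).
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  stage <- "load"
  summary <- list(seed = config$seed, alpha = config$alpha, B = config$B,
                  lambda = config$lambda)
  tryCatch({
    es <- if (!is.null(config$simulation)) {
      sim <- simulateDataset(config$simulation)
      truth_df <- data.frame(probeset_id = names(sim$truth$beta),
                             beta = sim$truth$beta, mu = sim$truth$mu,
                             is_null = sim$truth$is_null)
      .write_tsv(truth_df, out, "simulation_truth.tsv")
      sim$es
    } else {
      readExpressionTSV(config$matrix_path, config$annotation_path)
    }
    summary$n_probesets <- nrow(es)
    summary$n_samples <- ncol(es)

    stage <- "subset"
    paired <- selectPairedTissues(es, config$min_group_size)
    summary$n_paired_samples <- ncol(paired)
    summary$n_paired_tissues <- length(unique(tissueType(paired)))

    stage <- "map"
    for (tn in config$top_n) {
      red <- if (is.finite(tn)) selectMostVariable(paired, min(tn, nrow(paired)))
             else paired
      tag <- if (is.finite(tn)) sprintf("top%d", as.integer(tn)) else "all"
      sim_m <- groupSimilarity(red)
      .write_tsv(as.data.frame(sim_m), out, sprintf("group_similarity_%s.tsv", tag))
      gm <- groupMeanMatrix(red)
      .write_tsv(as.data.frame(gm), out, sprintf("group_means_%s.tsv", tag))
      exportNewick(clusterGroups(sim_m),
                   file.path(out, sprintf("dendrogram_%s.nwk", tag)))
    }
    pca <- pcaMap(paired, k = 3L)
    pca_df <- data.frame(sample_id = rownames(pca$scores), pca$scores)
    pca_path <- file.path(out, "pca_scores.tsv")
    writeLines(paste0("# variance_fractions\t",
                      paste(sprintf("%.6f", pca$variance_fractions),
                            collapse = "\t")), pca_path)
    suppressWarnings(write.table(pca_df, pca_path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    summary$pca_variance_fractions <- pca$variance_fractions

    stage <- "bgv"
    vs <- betweenGroupVariance(paired, grouping = "tissue_status")
    writeVariabilityTSV(vs, file.path(out, "variability.tsv"))
    thr <- bgvOutlierThreshold(vs)
    summary$bgv_threshold <- thr$threshold
    summary$bgv_outlier_fraction <- mean(thr$flags)
    summary$no_deviation_fraction <- mean(vs$deviation_count == 0)

    stage <- "fit"
    sig <- fitAll(paired, alpha = config$alpha)
    .write_tsv(significanceTable(sig), out, "significance_table.tsv")
    volcanoExport(sig, file.path(out, "volcano.tsv"))
    summary$probesets_tested <- nrow(significanceTable(sig))
    summary$n_nonconverged <- sig@n_nonconverged
    summary$S <- sum(significanceTable(sig)$significant, na.rm = TRUE)
    summary$df <- significanceTable(sig)$df[1L]

    stage <- "permute"
    perm <- runPermutationTest(paired, B = config$B, alpha = config$alpha,
                               seed = child_seed(config$seed, "permute"),
                               lambda = config$lambda, observed = sig)
    perm_df <- data.frame(probeset_id = names(perm@empirical_p),
                          empirical_p = perm@empirical_p,
                          empirical_p_adjusted = perm@empirical_p_adjusted,
                          skipped_draws = perm@skipped_draws)
    .write_tsv(perm_df, out, "permutation_summary.tsv")
    qqExport(significanceTable(sig)$p_adjusted, perm@perm_p_adjusted,
             file.path(out, "qq_observed_vs_permuted.tsv"))
    writeLines(c("permutation run log",
                 sprintf("seed\t%d", perm@seed),
                 sprintf("B\t%d", perm@B),
                 sprintf("F_hat\t%.8g", perm@F_hat),
                 sprintf("sig_counts\t%s",
                         paste(perm@sig_counts, collapse = ",")),
                 sprintf("total_skipped_draws\t%d", sum(perm@skipped_draws))),
               file.path(out, "permutation_log.txt"))
    summary$F_hat <- perm@F_hat
    summary$pi0 <- perm@pi0
    summary$fdr_estimate <- perm@fdr_estimate
    summary$permutation_significant <-
      sum(perm@empirical_p_adjusted < config$alpha, na.rm = TRUE)

    stage <- "validate"
    if (!is.null(config$mapping_path)) {
      mapping <- readGeneMapping(config$mapping_path)
      sig_ps <- significanceTable(sig)$probeset_id[
        significanceTable(sig)$significant %in% TRUE]
      calls <- collapseToGenes(sig_ps, mapping)
      summary$unique_genes <- length(calls$unique_genes)
      summary$multi_matchings <- length(calls$multi_matching)
      summary$unmapped_probesets <- calls$unmapped_probeset_count
      if (!is.null(config$gene_sets_path)) {
        sets <- readGeneSetsGMT(config$gene_sets_path)
        universe <- if (!is.null(config$universe_path))
          readLines(config$universe_path)
        else sort(unique(unlist(mapping, use.names = FALSE)))
        ora <- overrepresentation(intersect(calls$unique_genes, universe),
                                  sets, universe)
        .write_tsv(ora, out, "list_validation.tsv")
      }
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
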