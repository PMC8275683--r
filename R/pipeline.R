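#' Assemble a full pipeline configuration
#'
#' All tunable parameters of the binarize -> pairs -> network -> paths ->
#' score -> evaluate chain, with the package defaults. The resolved
#' configuration is embedded in every run's output directory so results are
#' reproducible from the artifacts alone.
#'
#' @param margin StepMiner noise margin (log2 units).
#' @param SThr,pThr Sparse-quadrant thresholds.
#' @param min_frac,min_count Dynamic-range filter bounds.
#' @param edge_support_min Minimum cluster-edge support fraction.
#' @param min_cluster_size Minimum cluster size.
#' @param max_len Maximum path length (clusters).
#' @param healthy_label,disease_label Annotation class labels.
#' @param teer_cutoffs TEER response bin edges (percent).
#' @param seed Seed for any stochastic steps.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(margin = 0.5, SThr = 3, pThr = 0.1,
                            min_frac = 0.05, min_count = 3L,
                            edge_support_min = 0.5, min_cluster_size = 3L,
                            max_len = 5L, healthy_label = "healthy",
                            disease_label = "disease",
                            teer_cutoffs = c(25, 75), seed = 1L) {
  structure(list(margin = margin, SThr = SThr, pThr = pThr,
                 min_frac = min_frac, min_count = min_count,
                 edge_support_min = edge_support_min,
                 min_cluster_size = min_cluster_size, max_len = max_len,
                 healthy_label = healthy_label,
                 disease_label = disease_label,
                 teer_cutoffs = teer_cutoffs, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full Boolean-implication-network pipeline
#'
#' Executes binarize -> all-pairs implication -> equivalence clustering ->
#' cluster network -> orientation -> path enumeration -> path selection ->
#' sample scoring -> evaluation, logging per-stage counts. When `out_dir`
#' is given, writes `network.json`, `selection.json`, `scores.tsv`,
#' `report.json` and `config.json`. The run is deterministic for a fixed
#' config.
#'
#' @param matrix Expression matrix (genes x samples) or a path to a TSV
#'   readable by [read_expression()].
#' @param annotation Annotation data frame or a TSV path for
#'   [read_annotation()].
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Log per-stage counts via `message()` (default `TRUE`).
#' @return A list of class `pipeline_report`: `ternary`, `pairs`, `network`,
#'   `paths`, `selection`, `scores`, `evaluation`, `report` (a summary
#'   list: counts, chosen path, AUC, Fisher p), `config`.
#' @export
run_pipeline <- function(matrix, annotation, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  if (is.character(matrix)) {
    matrix <- stage("read_expression", read_expression(matrix))
  }
  if (is.character(annotation)) {
    annotation <- stage("read_annotation", read_annotation(annotation))
  }
  if (!nrow(matrix)) stop("pipeline stage 'read_expression' failed: ",
                          "no genes in expression matrix", call. = FALSE)
  log_("expression: %d genes x %d samples", nrow(matrix), ncol(matrix))

  ternary <- stage("binarize", binarize_matrix(matrix, margin = config$margin))
  genes <- stage("dynamic_range_filter",
                 dynamic_range_filter(ternary, config$min_frac,
                                      config$min_count))
  log_("binarize: %d bimodal genes kept of %d", length(genes), nrow(matrix))

  pairs <- stage("pairs", all_pairs_network(ternary, genes,
                                            SThr = config$SThr,
                                            pThr = config$pThr))
  log_("pairs: %d implication edges", nrow(pairs))

  eq <- stage("equivalence_graph", build_equivalence_graph(pairs))
  clusters <- stage("cluster_genes",
                    cluster_genes(eq, config$min_cluster_size))
  log_("clusters: %d (sizes %s)", length(clusters),
       paste(vapply(clusters, function(c) length(c$members), integer(1)),
             collapse = "/"))
  if (!length(clusters)) {
    stop("pipeline stage 'cluster_genes' failed: no clusters of size >= ",
         config$min_cluster_size, call. = FALSE)
  }

  network <- stage("cluster_network",
                   build_cluster_network(clusters, pairs,
                                         config$edge_support_min))
  network <- stage("orient_clusters",
                   orient_clusters(network, matrix, annotation,
                                   ternary$fits,
                                   healthy_label = config$healthy_label,
                                   disease_label = config$disease_label))
  log_("network: %d directed edges", nrow(network$edges))

  paths <- stage("enumerate_paths",
                 enumerate_paths(network, max_len = config$max_len))
  log_("paths: %d candidates (max_len %d)", length(paths), config$max_len)
  if (!length(paths)) {
    stop("pipeline stage 'enumerate_paths' failed: no admissible paths",
         call. = FALSE)
  }

  normalized <- stage("normalize", normalize_expression(matrix, ternary$fits))
  selection <- stage("select_best_path",
                     select_best_path(paths, normalized, network$clusters,
                                      annotation,
                                      positive_label = config$healthy_label))
  scores <- stage("score_samples",
                  score_samples(selection$chosen, normalized,
                                network$clusters))
  evaluation <- stage("evaluate",
                      evaluate_signature(matrix, annotation,
                                         selection$chosen,
                                         clusters = network$clusters,
                                         positive_label =
                                           config$healthy_label,
                                         margin = config$margin))
  log_("chosen path: %s (AUC %.3f, Fisher p %.3g)",
       paste(selection$chosen$clusters, collapse = " -> "),
       evaluation$auc, evaluation$fisher_p)

  report <- list(
    n_genes = nrow(matrix), n_samples = ncol(matrix),
    n_bimodal = length(genes), n_pairs = nrow(pairs),
    n_clusters = length(clusters), n_edges = nrow(network$edges),
    n_paths = length(paths),
    chosen_path = selection$chosen$clusters,
    auc = evaluation$auc, fisher_p = evaluation$fisher_p)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(network, file.path(out_dir, "network.json"))
    jsonlite::write_json(
      list(table = selection$table,
           chosen_index = selection$chosen_index,
           chosen = selection$chosen$clusters),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(sample_id = names(scores), score = scores,
                 stringsAsFactors = FALSE),
      file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(ternary = ternary, pairs = pairs, network = network,
                 paths = paths, selection = selection, scores = scores,
                 evaluation = evaluation, report = report, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("pipeline run: %d genes x %d samples; %d bimodal, ",
                     "%d pairs, %d clusters, %d edges, %d paths\n"),
              r$n_genes, r$n_samples, r$n_bimodal, r$n_pairs, r$n_clusters,
              r$n_edges, r$n_paths))
  cat(sprintf("chosen path %s: AUC %.3f, Fisher p %.3g\n",
              paste(r$chosen_path, collapse = " -> "), r$auc, r$fisher_p))
  invisible(x)
}
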