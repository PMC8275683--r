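#' Build the undirected gene-equivalence graph
#'
#' One vertex per gene appearing in the pair table, one undirected edge per
#' `EQUIVALENT` pair.
#'
#' @param results An `implication_results` data frame from
#'   [all_pairs_network()].
#' @return An undirected [igraph][igraph::make_graph] graph.
#' @export
build_equivalence_graph <- function(results) {
  genes <- sort(unique(c(results$gene_a, results$gene_b)))
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  eq <- results[results$relation == "EQUIVALENT", , drop = FALSE]
  if (nrow(eq)) {
    g <- igraph::add_edges(g, rbind(match(eq$gene_a, genes),
                                    match(eq$gene_b, genes)))
  }
  g
}

#' Group genes into equivalence clusters
#'
#' Greedy agglomeration: genes are visited in descending equivalence-degree
#' order (ties by gene id); a gene joins an existing cluster iff it has
#' equivalence edges to at least half of the cluster's current members —
#' when several clusters qualify, the one with the highest connection
#' fraction wins, ties going to the earliest-seeded cluster — otherwise it
#' seeds a new cluster. Clusters below `min_cluster_size` are discarded.
#' Surviving clusters are labeled `C1, C2, ...` by decreasing size (ties by
#' seeding order), so `C1` is always the largest module.
#'
#' @param equiv_graph Undirected graph from [build_equivalence_graph()].
#' @param min_cluster_size Minimum members to keep a cluster (default 3).
#' @return A list of clusters, each a list with `cluster_id`, `members`
#'   (sorted character vector), `side` (`"unassigned"` until
#'   [orient_clusters()]), `healthy_mean`, `disease_mean`.
#' @export
cluster_genes <- function(equiv_graph, min_cluster_size = 3L) {
  genes <- igraph::V(equiv_graph)$name
  if (!length(genes)) return(list())
  deg <- igraph::degree(equiv_graph)
  ord <- order(-deg, genes)
  adj <- igraph::as_adj_list(equiv_graph)
  neighbors <- lapply(adj, function(v) genes[as.integer(v)])
  names(neighbors) <- genes

  members <- list()  # clusters in seeding order
  for (g in genes[ord]) {
    nb <- neighbors[[g]]
    frac <- vapply(members, function(m) mean(m %in% nb), numeric(1))
    ok <- which(frac >= 0.5)
    if (length(ok)) {
      best <- ok[which.max(frac[ok])]  # first max: earliest cluster on ties
      members[[best]] <- c(members[[best]], g)
    } else {
      members[[length(members) + 1L]] <- g
    }
  }
  sizes <- lengths(members)
  keep <- which(sizes >= min_cluster_size)
  keep <- keep[order(-sizes[keep], keep)]
  lapply(seq_along(keep), function(i) {
    list(cluster_id = paste0("C", i),
         members = sort(members[[keep[[i]]]]),
         side = "unassigned",
         healthy_mean = NA_real_, disease_mean = NA_real_)
  })
}

new_cluster_network <- function(clusters, edges) {
  structure(list(clusters = clusters, edges = edges),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("cluster network: %d clusters, %d directed edges\n",
              length(x$clusters), nrow(x$edges)))
  for (cl in x$clusters) {
    cat(sprintf("  %s: %d genes [%s]\n", cl$cluster_id,
                length(cl$members), cl$side))
  }
  invisible(x)
}

# Per-pair implication strength: the S of the sparse quadrant(s) defining
# the relation (minimum for the symmetric classes). Invariant under
# argument swap.
pair_strength <- function(results) {
  s <- rep.int(NA_real_, nrow(results))
  r <- results$relation
  s[r == "LOW_LOW"] <- results$S01[r == "LOW_LOW"]
  s[r == "LOW_HIGH"] <- results$S00[r == "LOW_HIGH"]
  s[r == "HIGH_HIGH"] <- results$S10[r == "HIGH_HIGH"]
  s[r == "HIGH_LOW"] <- results$S11[r == "HIGH_LOW"]
  s[r == "EQUIVALENT"] <- pmin(results$S01, results$S10)[r == "EQUIVALENT"]
  s[r == "OPPOSITE"] <- pmin(results$S00, results$S11)[r == "OPPOSITE"]
  s
}

#' Build the directed cluster-level network
#'
#' For every ordered pair of clusters, all cross-cluster gene-pair relations
#' are tallied (pairs absent from the relation table count as `NONE`). The
#' majority non-`NONE` relation becomes a directed edge iff its support —
#' the fraction of all cross pairs carrying it — reaches
#' `edge_support_min`; ties between relations are broken by the higher mean
#' implication statistic.
#'
#' @param clusters Cluster list from [cluster_genes()].
#' @param results `implication_results` from [all_pairs_network()].
#' @param edge_support_min Minimum support fraction (default 0.5).
#' @return A `cluster_network` with the clusters and an edge data frame
#'   (`from`, `to`, `relation`, `support`, `mean_S`).
#' @export
build_cluster_network <- function(clusters, results, edge_support_min = 0.5) {
  strength <- pair_strength(results)
  key <- paste(results$gene_a, results$gene_b, sep = "\r")
  edges <- list()
  for (i in seq_along(clusters)) {
    for (j in seq_along(clusters)) {
      if (i == j) next
      gi <- clusters[[i]]$members
      gj <- clusters[[j]]$members
      # stored orientation has gene_a < gene_b; build both key directions
      grid <- expand.grid(a = gi, b = gj, stringsAsFactors = FALSE)
      fwd <- grid$a < grid$b
      k <- ifelse(fwd, paste(grid$a, grid$b, sep = "\r"),
                  paste(grid$b, grid$a, sep = "\r"))
      hit <- match(k, key)
      rel <- ifelse(is.na(hit), "NONE", results$relation[hit])
      rel[!fwd] <- converse_relation(rel[!fwd])
      str_ <- ifelse(is.na(hit), NA_real_, strength[hit])
      total <- nrow(grid)
      tal <- table(rel[rel != "NONE"])
      if (!length(tal)) next
      support <- as.numeric(tal) / total
      cand <- which(support >= edge_support_min)
      if (!length(cand)) next
      if (length(cand) > 1L) {
        ms <- vapply(names(tal)[cand], function(r) {
          mean(str_[rel == r], na.rm = TRUE)
        }, numeric(1))
        cand <- cand[order(-support[cand], -ms)][1L]
      }
      r_win <- names(tal)[cand]
      edges[[length(edges) + 1L]] <- data.frame(
        from = clusters[[i]]$cluster_id, to = clusters[[j]]$cluster_id,
        relation = r_win, support = support[cand],
        mean_S = mean(str_[rel == r_win], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edge_frame()
  rownames(edges) <- NULL
  new_cluster_network(clusters, edges)
}

#' Orient clusters toward the healthy or disease side
#'
#' A cluster is healthy-side iff the mean threshold-centered expression
#' (`x - t`, using each member gene's step threshold) over healthy samples
#' exceeds the same mean over disease samples; the reverse gives
#' disease-side; exact ties, missing classes or missing members leave the
#' cluster `unassigned`.
#'
#' @param clusters Cluster list (or a `cluster_network`, whose clusters are
#'   updated in place).
#' @param matrix Expression matrix (genes x samples).
#' @param annotation Data frame with `sample_id` and `class_label`.
#' @param fits Per-gene fit table from [binarize_matrix()] (`$fits`).
#' @param healthy_label,disease_label Class labels to compare
#'   (defaults `"healthy"`, `"disease"`).
#' @return The input with each cluster's `side`, `healthy_mean` and
#'   `disease_mean` filled in.
#' @export
orient_clusters <- function(clusters, matrix, annotation, fits,
                            healthy_label = "healthy",
                            disease_label = "disease") {
  is_net <- inherits(clusters, "cluster_network")
  cl_list <- if (is_net) clusters$clusters else clusters
  h_samples <- annotation$sample_id[annotation$class_label == healthy_label]
  d_samples <- annotation$sample_id[annotation$class_label == disease_label]
  h_samples <- intersect(h_samples, colnames(matrix))
  d_samples <- intersect(d_samples, colnames(matrix))
  cl_list <- lapply(cl_list, function(cl) {
    mem <- intersect(cl$members, rownames(matrix))
    if (!length(h_samples) || !length(d_samples) || !length(mem)) {
      cl$side <- "unassigned"
      return(cl)
    }
    centered <- matrix[mem, , drop = FALSE] -
      fits[mem, "threshold"]
    cl$healthy_mean <- mean(centered[, h_samples, drop = FALSE])
    cl$disease_mean <- mean(centered[, d_samples, drop = FALSE])
    cl$side <- if (cl$healthy_mean > cl$disease_mean) "healthy"
               else if (cl$healthy_mean < cl$disease_mean) "disease"
               else "unassigned"
    cl
  })
  if (is_net) {
    clusters$clusters <- cl_list
    clusters
  } else {
    cl_list
  }
}
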