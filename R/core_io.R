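#' Read a gene-expression matrix from a tab-separated file
#'
#' Expression tables are genes x samples, tab-separated, with sample
#' identifiers in the first (header) row and gene identifiers in the first
#' column. Values are expected to be log2-scale intensities or abundances;
#' the loader never renormalizes, but `log2_transform = TRUE` applies
#' `log2(x + 1)` for raw counts.
#'
#' Missing cells are resolved at read time: `"drop_gene"` removes any gene
#' (row) containing a missing value, `"impute_row_mean"` replaces missing
#' values with the row mean. The number of affected genes is reported via
#' `message()`.
#'
#' @param path Path to the TSV file.
#' @param missing_policy One of `"drop_gene"` (default) or
#'   `"impute_row_mean"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` after loading.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names and no missing values.
#' @export
read_expression <- function(path,
                            missing_policy = c("drop_gene", "impute_row_mean"),
                            log2_transform = FALSE) {
  missing_policy <- match.arg(missing_policy)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    stop("empty expression file: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header at line 1: expected at least one sample column")
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_expected <- length(header)
  bad <- which(vapply(fields, length, integer(1)) != ncol_expected)
  if (length(bad)) {
    stop("parse error at line ", bad[[1L]] + 1L,
         ": expected ", ncol_expected, " fields")
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  values <- do.call(rbind, lapply(fields, function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }))
  dimnames(values) <- list(gene_ids, sample_ids)

  n_missing_genes <- sum(apply(values, 1L, anyNA))
  if (n_missing_genes > 0L) {
    if (missing_policy == "drop_gene") {
      values <- values[!apply(values, 1L, anyNA), , drop = FALSE]
      message(n_missing_genes, " gene(s) dropped due to missing values")
    } else {
      for (i in which(apply(values, 1L, anyNA))) {
        row <- values[i, ]
        row[is.na(row)] <- mean(row, na.rm = TRUE)
        values[i, ] <- row
      }
      message(n_missing_genes, " gene(s) imputed with their row mean")
    }
  }
  if (log2_transform) values <- log2(values + 1)
  values
}

#' Write a gene-expression matrix to a tab-separated file
#'
#' Inverse of [read_expression()]: first column `gene_id`, remaining columns
#' one per sample.
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' TSV with header `sample_id<TAB>class_label[<TAB>covariate...]`. Each
#' annotated sample must carry a non-empty class label.
#'
#' @param path Path to the TSV file.
#' @return A data frame with at least columns `sample_id` and `class_label`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("sample_id", "class_label") %in% names(ann))) {
    stop("annotation file must have columns 'sample_id' and 'class_label'")
  }
  if (any(!nzchar(ann$class_label) | is.na(ann$class_label))) {
    stop("empty class_label for sample(s): ",
         paste(ann$sample_id[!nzchar(ann$class_label) | is.na(ann$class_label)],
               collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample ids in annotation")
  }
  ann
}

#' Write a sample-annotation table
#' @param annotation Data frame with `sample_id`, `class_label` and optional
#'   covariate columns.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>gene...`.
#' Empty lines are skipped.
#'
#' @param path Path to the GMT file.
#' @return A named list; each element is a list with `name`, `description`
#'   and a character vector `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- lapply(keep, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set '", f[[1L]], "' at line ", i,
                             " has no genes")
    list(name = f[[1L]], description = f[[2L]], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets A list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a cluster network
#'
#' JSON is the canonical on-disk schema (nodes with memberships and sides,
#' edges with relation, support fraction and mean statistic); GraphML is
#' provided for interchange with graph tools and stores cluster memberships
#' as comma-joined strings.
#'
#' @param network A `cluster_network` object from [build_cluster_network()].
#' @param path Output path.
#' @param format `"json"` or `"graphml"`.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cluster_network"))
  if (format == "json") {
    payload <- list(
      clusters = lapply(network$clusters, function(cl) {
        list(cluster_id = cl$cluster_id, members = as.list(cl$members),
             side = cl$side, healthy_mean = cl$healthy_mean,
             disease_mean = cl$disease_mean)
      }),
      edges = if (nrow(network$edges)) network$edges else list()
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Deserialize a cluster network written by [write_network()]
#' @param path Input path.
#' @param format `"json"` or `"graphml"`.
#' @return A `cluster_network` object.
#' @export
read_network <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
    clusters <- lapply(payload$clusters, function(cl) {
      list(cluster_id = cl$cluster_id,
           members = as.character(unlist(cl$members)),
           side = cl$side,
           healthy_mean = if (is.null(cl$healthy_mean)) NA_real_ else
             as.numeric(cl$healthy_mean),
           disease_mean = if (is.null(cl$disease_mean)) NA_real_ else
             as.numeric(cl$disease_mean))
    })
    edges <- payload$edges
    if (length(edges)) {
      edges <- do.call(rbind, lapply(edges, function(e) {
        data.frame(from = e$from, to = e$to, relation = e$relation,
                   support = as.numeric(e$support),
                   mean_S = as.numeric(e$mean_S),
                   stringsAsFactors = FALSE)
      }))
    } else {
      edges <- empty_edge_frame()
    }
    new_cluster_network(clusters, edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    igraph_to_network(g)
  }
}

network_to_igraph <- function(network) {
  ids <- vapply(network$clusters, `[[`, character(1), "cluster_id")
  sides <- vapply(network$clusters, `[[`, character(1), "side")
  members <- vapply(network$clusters, function(cl) {
    paste(cl$members, collapse = ",")
  }, character(1))
  hmean <- vapply(network$clusters, function(cl) {
    as.numeric(cl$healthy_mean %||% NA_real_)
  }, numeric(1))
  dmean <- vapply(network$clusters, function(cl) {
    as.numeric(cl$disease_mean %||% NA_real_)
  }, numeric(1))
  g <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "side", value = sides)
  g <- igraph::set_vertex_attr(g, "members", value = members)
  g <- igraph::set_vertex_attr(g, "healthy_mean", value = hmean)
  g <- igraph::set_vertex_attr(g, "disease_mean", value = dmean)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(match(network$edges$from, ids),
                                    match(network$edges$to, ids)))
    g <- igraph::set_edge_attr(g, "relation", value = network$edges$relation)
    g <- igraph::set_edge_attr(g, "support", value = network$edges$support)
    g <- igraph::set_edge_attr(g, "mean_S", value = network$edges$mean_S)
  }
  g
}

igraph_to_network <- function(g) {
  ids <- igraph::vertex_attr(g, "name")
  clusters <- lapply(seq_along(ids), function(i) {
    mem <- igraph::vertex_attr(g, "members")[[i]]
    list(cluster_id = ids[[i]],
         members = if (nzchar(mem)) strsplit(mem, ",", fixed = TRUE)[[1L]]
                   else character(0),
         side = igraph::vertex_attr(g, "side")[[i]],
         healthy_mean = igraph::vertex_attr(g, "healthy_mean")[[i]],
         disease_mean = igraph::vertex_attr(g, "disease_mean")[[i]])
  })
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    edges <- data.frame(from = el[, 1L], to = el[, 2L],
                        relation = igraph::edge_attr(g, "relation"),
                        support = igraph::edge_attr(g, "support"),
                        mean_S = igraph::edge_attr(g, "mean_S"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edge_frame()
  }
  new_cluster_network(clusters, edges)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

empty_edge_frame <- function() {
  data.frame(from = character(0), to = character(0), relation = character(0),
             support = numeric(0), mean_S = numeric(0),
             stringsAsFactors = FALSE)
}
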