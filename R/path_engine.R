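#' Enumerate simple continuum paths through the cluster network
#'
#' Depth-first enumeration of all simple directed paths of 2 to `max_len`
#' clusters whose every edge carries an admissible relation. `EQUIVALENT`
#' edges are admissible only between clusters on the same (assigned) side,
#' since an equivalence crossing the healthy/disease divide cannot encode
#' progression. Output order is lexicographic over the cluster-id sequence;
#' enumeration stops (with a warning) after `max_paths` paths.
#'
#' @param network An oriented `cluster_network`.
#' @param max_len Maximum number of clusters per path (default 5).
#' @param admissible_relations Relations allowed on path edges.
#' @param max_paths Hard cap on enumerated paths (default 1e5).
#' @return A list of `boolean_path` objects (fields `clusters`, `relations`,
#'   `weights`; weights are filled at scoring time when `NULL`).
#' @export
enumerate_paths <- function(network, max_len = 5L,
                            admissible_relations = c("OPPOSITE", "LOW_HIGH",
                                                     "HIGH_LOW",
                                                     "EQUIVALENT"),
                            max_paths = 1e5) {
  if (max_len < 2L) stop("max_len must be at least 2")
  stopifnot(inherits(network, "cluster_network"))
  sides <- vapply(network$clusters, `[[`, character(1), "side")
  names(sides) <- vapply(network$clusters, `[[`, character(1), "cluster_id")
  e <- network$edges
  if (nrow(e)) {
    ok <- e$relation %in% admissible_relations
    same_side <- sides[e$from] == sides[e$to] &
      sides[e$from] != "unassigned"
    ok <- ok & (e$relation != "EQUIVALENT" | same_side)
    e <- e[ok, , drop = FALSE]
  }
  nodes <- sort(names(sides))
  out_edges <- lapply(nodes, function(v) {
    idx <- which(e$from == v)
    idx[order(e$to[idx])]
  })
  names(out_edges) <- nodes

  paths <- list()
  truncated <- FALSE
  walk <- function(chain, rels) {
    if (truncated) return()
    if (length(chain) >= 2L) {
      paths[[length(paths) + 1L]] <<- new_boolean_path(chain, rels)
      if (length(paths) >= max_paths) {
        truncated <<- TRUE
        return()
      }
    }
    if (length(chain) >= max_len) return()
    v <- chain[[length(chain)]]
    for (idx in out_edges[[v]]) {
      w <- e$to[[idx]]
      if (w %in% chain) next  # simple paths only
      walk(c(chain, w), c(rels, e$relation[[idx]]))
      if (truncated) return()
    }
  }
  for (v in nodes) {
    walk(v, character(0))
    if (truncated) break
  }
  if (truncated) {
    warning("path enumeration truncated at ", max_paths, " paths")
  }
  keys <- vapply(paths, function(p) paste(p$clusters, collapse = "\r"),
                 character(1))
  paths[order(keys)]
}

new_boolean_path <- function(clusters, relations, weights = NULL) {
  stopifnot(length(relations) == length(clusters) - 1L ||
              (length(clusters) == 1L && !length(relations)))
  structure(list(clusters = clusters, relations = relations,
                 weights = weights), class = "boolean_path")
}

#' Construct a Boolean path by hand
#' @param clusters Ordered cluster ids.
#' @param relations Edge relations along the path (length one less than
#'   `clusters`); `NULL` for unannotated chains.
#' @param weights Optional per-cluster weights.
#' @export
boolean_path <- function(clusters, relations = NULL, weights = NULL) {
  if (is.null(relations)) {
    relations <- rep.int(NA_character_, max(length(clusters) - 1L, 0L))
  }
  new_boolean_path(clusters, relations, weights)
}

#' @export
print.boolean_path <- function(x, ...) {
  if (length(x$clusters) > 1L) {
    rel <- ifelse(is.na(x$relations), "?", x$relations)
    cat(paste0(x$clusters[-length(x$clusters)], " -[", rel, "]-> ",
               collapse = ""), x$clusters[[length(x$clusters)]], "\n")
  } else {
    cat(x$clusters, "\n")
  }
  invisible(x)
}

#' Threshold-center and scale an expression matrix
#'
#' Each gene is transformed to `(x - t) / s`, where `t` is its step
#' threshold and `s` its standard deviation across samples (`s = 1` for
#' constant genes), so the binarization threshold maps to 0 for every gene
#' and cluster averages are comparable across genes.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param fits Per-gene fit table from [binarize_matrix()] (`$fits`); must
#'   cover every gene in `matrix`.
#' @return Normalized matrix, same shape and dimnames.
#' @export
normalize_expression <- function(matrix, fits) {
  missing <- setdiff(rownames(matrix), fits$gene_id)
  if (length(missing)) {
    stop("no step fit for gene(s): ", paste(missing, collapse = ", "))
  }
  t_ <- fits[rownames(matrix), "threshold"]
  s <- fits[rownames(matrix), "sd"]
  s[!is.finite(s) | s == 0] <- 1
  (matrix - t_) / s
}

# Resolve a path's cluster weights: explicit > side-signed defaults
# (healthy +1, disease -1, unassigned 0).
path_weights <- function(path, clusters) {
  if (!is.null(path$weights)) {
    stopifnot(length(path$weights) == length(path$clusters))
    return(path$weights)
  }
  sides <- vapply(clusters, `[[`, character(1), "side")
  names(sides) <- vapply(clusters, `[[`, character(1), "cluster_id")
  w <- c(healthy = 1, disease = -1, unassigned = 0)[sides[path$clusters]]
  unname(w)
}

#' Composite per-sample continuum score along a path
#'
#' `score(s) = sum_i w_i * mean_{g in cluster_i} normalized[g, s]`. With the
#' default side-signed weights (healthy +1, disease -1) healthy samples
#' score high, so the score orders samples from disease to healthy along
#' the continuum.
#'
#' @param path A `boolean_path`.
#' @param normalized Matrix from [normalize_expression()].
#' @param clusters Cluster list (or `cluster_network`).
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(path, normalized, clusters) {
  if (inherits(clusters, "cluster_network")) clusters <- clusters$clusters
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  w <- path_weights(path, clusters)
  score <- numeric(ncol(normalized))
  for (i in seq_along(path$clusters)) {
    cl <- clusters[[match(path$clusters[[i]], ids)]]
    if (is.null(cl)) stop("unknown cluster: ", path$clusters[[i]])
    mem <- intersect(cl$members, rownames(normalized))
    if (!length(mem)) stop("cluster ", cl$cluster_id,
                           " has no genes in the matrix")
    score <- score + w[[i]] * colMeans(normalized[mem, , drop = FALSE])
  }
  names(score) <- colnames(normalized)
  score
}

#' Select the most label-discriminative path by linear regression
#'
#' For each candidate path the binary class label (coded 0/1 against
#' `positive_label`) is regressed on the per-sample path score by ordinary
#' least squares. The chosen path has the smallest coefficient p-value,
#' ties broken by the larger absolute coefficient.
#'
#' @param paths List of `boolean_path` candidates.
#' @param normalized Matrix from [normalize_expression()].
#' @param clusters Cluster list (or `cluster_network`).
#' @param annotation Data frame with `sample_id`, `class_label` (exactly two
#'   classes among scored samples).
#' @param positive_label Class coded 1; default `"healthy"` when present,
#'   otherwise the lexicographically first label.
#' @return A list of class `path_selection`: `table` (per-path coefficient,
#'   95% CI, p-value), `paths`, `chosen_index`, `chosen`.
#' @export
select_best_path <- function(paths, normalized, clusters, annotation,
                             positive_label = NULL) {
  if (!length(paths)) stop("no candidate paths")
  ann <- annotation[match(colnames(normalized), annotation$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotation missing for some samples")
  labs <- unique(ann$class_label)
  if (length(labs) < 2L) stop("need two classes, found: ",
                              paste(labs, collapse = ", "))
  if (is.null(positive_label)) {
    positive_label <- if ("healthy" %in% labs) "healthy" else sort(labs)[[1L]]
  }
  y <- as.numeric(ann$class_label == positive_label)
  rows <- lapply(seq_along(paths), function(i) {
    sc <- score_samples(paths[[i]], normalized, clusters)
    if (stats::sd(sc) == 0) {
      return(data.frame(path = i, coefficient = 0, ci_lo = NA_real_,
                        ci_hi = NA_real_, p_value = 1))
    }
    fit <- stats::lm(y ~ sc)
    # an exactly separating score is legitimate; silence the perfect-fit
    # warning and report p = 0 below
    co <- suppressWarnings(summary(fit))$coefficients
    ci <- suppressWarnings(stats::confint(fit, "sc", level = 0.95))
    p <- co["sc", "Pr(>|t|)"]
    if (is.nan(p)) p <- 0  # exact fit: zero residual variance
    data.frame(path = i, coefficient = co["sc", "Estimate"],
               ci_lo = ci[[1L]], ci_hi = ci[[2L]], p_value = p)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$p_value, -abs(tab$coefficient))
  chosen <- ord[[1L]]
  structure(list(table = tab, paths = paths, chosen_index = chosen,
                 chosen = paths[[chosen]],
                 positive_label = positive_label),
            class = "path_selection")
}

#' @export
print.path_selection <- function(x, ...) {
  cat(sprintf("path selection over %d candidates; chosen #%d (p = %.3g):\n",
              nrow(x$table), x$chosen_index,
              x$table$p_value[[x$chosen_index]]))
  print(x$chosen)
  invisible(x)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive sample outranks a
#' randomly chosen negative one, with ties counted 1/2 — the Mann-Whitney
#' statistic divided by `n_pos * n_neg`, computed from midranks.
#'
#' @param scores Numeric vector.
#' @param positive Logical vector (or 0/1) marking positive samples.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive), !anyNA(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table no more probable than the observed one (with the customary
#' `1 + 1e-7` tolerance on the probability comparison).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  if (sum(table) == 0) stop("all-zero table")
  m <- sum(table[1L, ])          # row-1 margin
  n <- sum(table[2L, ])          # row-2 margin
  k <- sum(table[, 1L])          # column-1 margin
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1L, 1L], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Evaluate a signature on a labeled cohort
#'
#' Scores every sample with either a Boolean path (see [score_samples()])
#' or an up/down gene-set pair (mean normalized expression of the up set
#' minus the down set), then reports the ROC-AUC of the score against the
#' class labels and the two-sided Fisher exact p of the thresholded
#' classification (score > `threshold` predicts the positive class).
#'
#' @param matrix Expression matrix (genes x samples).
#' @param annotation Data frame with `sample_id`, `class_label`.
#' @param signature Either a list `list(up = <genes>, down = <genes>)` or a
#'   `boolean_path` (then `clusters` is required).
#' @param clusters Cluster list, for path signatures.
#' @param positive_label Class expected to score high; default `"healthy"`
#'   when present, else the lexicographically first label.
#' @param threshold Score cut for the Fisher classification (default 0).
#' @param margin Binarization margin for the internal step fits.
#' @return List with `auc`, `fisher_p`, `scores`, `confusion`.
#' @export
evaluate_signature <- function(matrix, annotation, signature, clusters = NULL,
                               positive_label = NULL, threshold = 0,
                               margin = 0.5) {
  ann <- annotation[match(colnames(matrix), annotation$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotation missing for some samples")
  labs <- unique(ann$class_label)
  if (length(labs) < 2L) stop("need two classes")
  if (is.null(positive_label)) {
    positive_label <- if ("healthy" %in% labs) "healthy" else sort(labs)[[1L]]
  }
  tern <- binarize_matrix(matrix, margin = margin)
  normalized <- normalize_expression(matrix, tern$fits)
  if (inherits(signature, "boolean_path")) {
    if (is.null(clusters)) stop("path signatures need 'clusters'")
    scores <- score_samples(signature, normalized, clusters)
  } else {
    up <- intersect(signature$up, rownames(normalized))
    down <- intersect(signature$down, rownames(normalized))
    found <- length(up) + length(down)
    if (found < 2L) {
      missing <- setdiff(c(signature$up, signature$down), rownames(matrix))
      stop("fewer than 2 signature genes found in matrix; missing: ",
           paste(missing, collapse = ", "))
    }
    scores <- numeric(ncol(normalized))
    if (length(up)) scores <- scores +
        colMeans(normalized[up, , drop = FALSE])
    if (length(down)) scores <- scores -
        colMeans(normalized[down, , drop = FALSE])
    names(scores) <- colnames(normalized)
  }
  positive <- ann$class_label == positive_label
  predicted <- scores > threshold
  confusion <- matrix(c(sum(predicted & positive), sum(predicted & !positive),
                        sum(!predicted & positive),
                        sum(!predicted & !positive)),
                      2L, 2L, byrow = TRUE,
                      dimnames = list(predicted = c("positive", "negative"),
                                      actual = c("positive", "negative")))
  list(auc = roc_auc(scores, positive),
       fisher_p = fisher_exact_2x2(confusion),
       scores = scores, confusion = confusion)
}
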