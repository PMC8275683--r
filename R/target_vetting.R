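#' Filter a gene list for druggability annotations
#'
#' Keeps genes carrying *all* required tags in a user-supplied annotation
#' table (set-intersection semantics). The table is static — no live
#' ontology lookups — so runs are reproducible offline. Genes absent from
#' the table are excluded with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param annotation_table Data frame with columns `gene_id` and `tags`
#'   (comma-separated class tags such as `kinase`, `receptor`, `enzyme`,
#'   `stress-response`).
#' @param required_tags Tags a gene must carry; empty means no filtering.
#' @return Character vector of passing gene ids, input order preserved.
#' @export
filter_druggable <- function(genes, annotation_table,
                             required_tags = character(0)) {
  if (!length(required_tags)) return(genes)
  stopifnot(all(c("gene_id", "tags") %in% names(annotation_table)))
  absent <- setdiff(genes, annotation_table$gene_id)
  if (length(absent)) {
    warning("gene(s) absent from annotation table, excluded: ",
            paste(absent, collapse = ", "))
  }
  tag_list <- strsplit(annotation_table$tags, ",", fixed = TRUE)
  tag_list <- lapply(tag_list, trimws)
  names(tag_list) <- annotation_table$gene_id
  keep <- vapply(genes, function(g) {
    !is.null(tag_list[[g]]) && all(required_tags %in% tag_list[[g]])
  }, logical(1))
  genes[keep]
}

# Relations entailing "anchor high => target low" / "anchor high => target
# high". OPPOSITE and EQUIVALENT entail the respective asymmetric reading.
ANCHOR_LOW_RELATIONS <- c("HIGH_LOW", "OPPOSITE")
ANCHOR_HIGH_RELATIONS <- c("HIGH_HIGH", "EQUIVALENT")

#' Vet a candidate drug target against the continuum paths and an anchor
#'
#' A target is `predicted_success` when it (i) lies on the
#' epithelial-mesenchymal-transition path, (ii) lies on the
#' inflammation-fibrosis path, and (iii) carries a strong
#' "anchor high => target low" implication (`HIGH_LOW` or `OPPOSITE`) at
#' the sparse-quadrant thresholds — all three conjunctively under the
#' default rule. An "anchor high => target high" implication (`HIGH_HIGH`
#' or `EQUIVALENT`) marks the target `contraindicated` for antagonists
#' regardless of path membership. Everything else is `predicted_failure`.
#' `rule = "disjunctive"` instead predicts success when either the strong
#' implication or dual-path membership holds.
#'
#' @param target,anchor Gene ids present in the ternary matrix.
#' @param paths List with gene-id vectors `emt` and `fibrosis` (the genes of
#'   each continuum path's clusters).
#' @param ternary A `ternary_matrix`.
#' @param SThr,pThr Sparsity thresholds.
#' @param rule `"conjunctive"` (default) or `"disjunctive"`.
#' @return A list of class `target_record`: `gene_id`, `on_path_emt`,
#'   `on_path_fibrosis`, `anchor_relation` (an `implication_result`),
#'   `verdict`.
#' @export
vet_target <- function(target, anchor, paths, ternary, SThr = 3, pThr = 0.1,
                       rule = c("conjunctive", "disjunctive")) {
  rule <- match.arg(rule)
  stopifnot(all(c("emt", "fibrosis") %in% names(paths)))
  for (g in c(target, anchor)) {
    if (!g %in% rownames(ternary$labels)) {
      stop("gene not in ternary matrix: ", g)
    }
  }
  res <- classify_pair(ternary$labels[anchor, ], ternary$labels[target, ],
                       SThr = SThr, pThr = pThr,
                       gene_a = anchor, gene_b = target)
  on_emt <- target %in% paths$emt
  on_fib <- target %in% paths$fibrosis
  strong_low <- res$relation %in% ANCHOR_LOW_RELATIONS
  verdict <- if (res$relation %in% ANCHOR_HIGH_RELATIONS) {
    "contraindicated"
  } else if (rule == "conjunctive") {
    if (on_emt && on_fib && strong_low) "predicted_success"
    else "predicted_failure"
  } else {
    if (strong_low || (on_emt && on_fib)) "predicted_success"
    else "predicted_failure"
  }
  structure(list(gene_id = target, on_path_emt = on_emt,
                 on_path_fibrosis = on_fib, anchor_relation = res,
                 verdict = verdict),
            class = "target_record")
}

#' @export
print.target_record <- function(x, ...) {
  cat(sprintf("%s: %s (emt=%s, fibrosis=%s, anchor relation %s)\n",
              x$gene_id, x$verdict, x$on_path_emt, x$on_path_fibrosis,
              x$anchor_relation$relation))
  invisible(x)
}

#' Pairwise equivalence association among targets
#'
#' Flags every target pair related by `EQUIVALENT` — the appropriate
#' association for a set of same-direction (e.g., all anti-inflammatory)
#' targets, where high/low or opposite relations would be misleading.
#'
#' @param targets Gene ids present in the ternary matrix.
#' @param ternary A `ternary_matrix`.
#' @param SThr,pThr Sparsity thresholds.
#' @param approved_set Optional gene ids; the summary counts, per target,
#'   its equivalences with this set (excluding itself).
#' @return List with `matrix` (symmetric logical, `NA` diagonal) and
#'   `approved_equivalences` (named integer vector, if `approved_set`
#'   given).
#' @export
target_association <- function(targets, ternary, SThr = 3, pThr = 0.1,
                               approved_set = NULL) {
  missing <- setdiff(targets, rownames(ternary$labels))
  if (length(missing)) stop("targets not in matrix: ",
                            paste(missing, collapse = ", "))
  k <- length(targets)
  m <- matrix(FALSE, k, k, dimnames = list(targets, targets))
  diag(m) <- NA
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        rel <- classify_pair(ternary$labels[targets[[i]], ],
                             ternary$labels[targets[[j]], ],
                             SThr = SThr, pThr = pThr)$relation
        m[i, j] <- m[j, i] <- rel == "EQUIVALENT"
      }
    }
  }
  out <- list(matrix = m)
  if (!is.null(approved_set)) {
    appr <- intersect(approved_set, targets)
    out$approved_equivalences <- vapply(targets, function(g) {
      others <- setdiff(appr, g)
      if (!length(others)) 0L else sum(m[g, others], na.rm = TRUE)
    }, integer(1))
  }
  out
}

#' Classify organoid barrier response from the TEER increase
#'
#' Percent increase in trans-epithelial electrical resistance (TEER) after
#' treatment, relative to untreated, is binned at 25 and 75:
#' `<= 25` nonresponder, `(25, 75]` responder, `> 75` high responder.
#'
#' @param teer_increase_pct Numeric vector of percent TEER increases.
#' @param cutoffs Bin edges (default `c(25, 75)`).
#' @return Factor with levels `nonresponder`, `responder`, `high_responder`.
#' @export
classify_response <- function(teer_increase_pct, cutoffs = c(25, 75)) {
  stopifnot(length(cutoffs) == 2L, all(is.finite(teer_increase_pct)))
  cut(teer_increase_pct, breaks = c(-Inf, cutoffs, Inf),
      labels = c("nonresponder", "responder", "high_responder"),
      right = TRUE)
}

#' Read a TEER response table
#'
#' TSV with columns `line_id`, `disease` (`healthy`/`UC`/`CD`) and
#' `teer_increase_pct`. The shipped fixture
#' `system.file("extdata", "table2_teer.tsv", package = "implinet")`
#' holds the published 18-line organoid cohort.
#'
#' @param path Path to the TSV file.
#' @return Data frame with an added `category` column from
#'   [classify_response()].
#' @export
read_teer_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "disease", "teer_increase_pct") %in% names(df)))
  df$category <- classify_response(df$teer_increase_pct)
  df
}

#' Summarize a classified organoid cohort
#'
#' Per-category counts, percentages (two decimals) and the disease-type
#' breakdown.
#'
#' @param records Data frame with `disease` and `category` columns (e.g.,
#'   from [read_teer_table()]); filter to the diseased lines first if
#'   healthy controls should be excluded.
#' @return List with `n`, `counts`, `pct`, `by_disease` (category x disease
#'   contingency table).
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  counts <- table(factor(records$category,
                         levels = c("nonresponder", "responder",
                                    "high_responder")))
  pct <- round(100 * as.numeric(counts) / nrow(records), 2)
  names(pct) <- names(counts)
  list(n = nrow(records),
       counts = stats::setNames(as.integer(counts), names(counts)),
       pct = pct,
       by_disease = table(records$category, records$disease))
}
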