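#' @name implication
#' @title Boolean implication relations between binarized gene pairs
#'
#' @description
#' After ternary binarization, every sample in which both genes are
#' unambiguously low (0) or high (2) falls into one quadrant of a 2x2 count
#' table. A quadrant is *sparse* when its observed count sits far below the
#' independence expectation:
#' \deqn{e_{ij} = row_i \cdot col_j / n, \quad
#'       S_{ij} = (e_{ij} - a_{ij}) / \sqrt{e_{ij}}, \quad
#'       p_{ij} = \tfrac12 (a_{ij}/row_i + a_{ij}/col_j)}
#' with sparsity declared when `S > SThr` and `p < pThr` (defaults 3 and
#' 0.1). The sparse-quadrant pattern determines one of six Boolean
#' implication relations (BIRs): four asymmetric (`LOW_LOW` meaning
#' "A low => B low", `LOW_HIGH`, `HIGH_HIGH`, `HIGH_LOW`) and two symmetric
#' (`EQUIVALENT` when both off-diagonal quadrants are sparse, `OPPOSITE`
#' when both diagonal quadrants are). Any other pattern — no sparse
#' quadrant, adjacent sparse pairs, or three or more sparse quadrants — is
#' `NONE`.
NULL

RELATIONS <- c("LOW_LOW", "LOW_HIGH", "HIGH_LOW", "HIGH_HIGH",
               "EQUIVALENT", "OPPOSITE", "NONE")

#' Count low/high quadrants for a gene pair
#'
#' Tallies samples where both ternary labels are decisive (0 or 2);
#' intermediate samples (1) are excluded. The first index is gene A's state
#' (0 = low, 1 = high), the second gene B's.
#'
#' @param ternary_a,ternary_b Integer vectors of 0/1/2 labels, equal length.
#' @return A list with integer fields `a00`, `a01`, `a10`, `a11` and `n`.
#' @export
count_quadrants <- function(ternary_a, ternary_b) {
  if (length(ternary_a) != length(ternary_b)) {
    stop("label vectors differ in length")
  }
  use <- ternary_a != 1L & ternary_b != 1L
  a <- ternary_a[use] == 2L
  b <- ternary_b[use] == 2L
  tab <- list(a00 = sum(!a & !b), a01 = sum(!a & b),
              a10 = sum(a & !b), a11 = sum(a & b))
  tab$n <- tab$a00 + tab$a01 + tab$a10 + tab$a11
  tab
}

#' Sparse-quadrant statistic for one quadrant
#'
#' @param table Quadrant counts from [count_quadrants()].
#' @param quadrant Integer pair `c(i, j)` with i = A state, j = B state
#'   (0 = low, 1 = high).
#' @param SThr,pThr Sparsity thresholds (defaults 3 and 0.1).
#' @return A list with `expected`, `S`, `p`, `sparse`. When the quadrant's
#'   row or column margin is zero the statistic is undefined: `S` and `p`
#'   are `NA` and `sparse` is `FALSE`.
#' @export
quadrant_statistic <- function(table, quadrant, SThr = 3, pThr = 0.1) {
  stopifnot(length(quadrant) == 2L, all(quadrant %in% 0:1))
  a <- table[[paste0("a", quadrant[[1L]], quadrant[[2L]])]]
  row_i <- if (quadrant[[1L]] == 0L) table$a00 + table$a01 else
    table$a10 + table$a11
  col_j <- if (quadrant[[2L]] == 0L) table$a00 + table$a10 else
    table$a01 + table$a11
  if (table$n == 0L || row_i == 0L || col_j == 0L) {
    return(list(expected = NA_real_, S = NA_real_, p = NA_real_,
                sparse = FALSE))
  }
  e <- row_i * col_j / table$n
  S <- (e - a) / sqrt(e)
  p <- 0.5 * (a / row_i + a / col_j)
  list(expected = e, S = S, p = p, sparse = S > SThr && p < pThr)
}

#' Map a sparse-quadrant pattern to its implication relation
#'
#' The mapping from the four sparsity flags to a relation class. Exactly six
#' patterns are admissible; everything else (no sparse quadrant, adjacent
#' pairs sharing a row or column, three or four sparse quadrants) is `NONE`.
#'
#' @param s00,s01,s10,s11 Logical sparsity flags (vectorized).
#' @return Character vector of relation names.
#' @export
relation_from_sparse <- function(s00, s01, s10, s11) {
  code <- 1L * s00 + 2L * s01 + 4L * s10 + 8L * s11
  out <- rep.int("NONE", length(code))
  out[code == 2L] <- "LOW_LOW"      # only a01 sparse: A low => B low
  out[code == 1L] <- "LOW_HIGH"     # only a00 sparse: A low => B high
  out[code == 4L] <- "HIGH_HIGH"    # only a10 sparse: A high => B high
  out[code == 8L] <- "HIGH_LOW"     # only a11 sparse: A high => B low
  out[code == 6L] <- "EQUIVALENT"   # a01 and a10 sparse
  out[code == 9L] <- "OPPOSITE"     # a00 and a11 sparse
  out
}

#' Relation seen from the swapped gene order
#'
#' `classify_pair(A, B) == LOW_LOW` iff `classify_pair(B, A) == HIGH_HIGH`;
#' `LOW_HIGH` and `HIGH_LOW` are self-converse; the symmetric relations and
#' `NONE` are unchanged.
#'
#' @param relation Character vector of relation names.
#' @return Character vector of converse relation names.
#' @export
converse_relation <- function(relation) {
  map <- c(LOW_LOW = "HIGH_HIGH", HIGH_HIGH = "LOW_LOW",
           LOW_HIGH = "LOW_HIGH", HIGH_LOW = "HIGH_LOW",
           EQUIVALENT = "EQUIVALENT", OPPOSITE = "OPPOSITE", NONE = "NONE")
  unname(map[relation])
}

#' Classify the Boolean implication relation of one gene pair
#'
#' @param ternary_a,ternary_b Integer 0/1/2 label vectors of equal length.
#' @param SThr,pThr Sparsity thresholds.
#' @param gene_a,gene_b Optional identifiers carried into the result.
#' @return A list of class `implication_result` with the quadrant `table`,
#'   the four quadrant `tests` (named `a00`, `a01`, `a10`, `a11`) and the
#'   `relation`.
#' @export
classify_pair <- function(ternary_a, ternary_b, SThr = 3, pThr = 0.1,
                          gene_a = "A", gene_b = "B") {
  tab <- count_quadrants(ternary_a, ternary_b)
  quads <- list(a00 = c(0L, 0L), a01 = c(0L, 1L),
                a10 = c(1L, 0L), a11 = c(1L, 1L))
  tests <- lapply(quads, function(q) {
    quadrant_statistic(tab, q, SThr = SThr, pThr = pThr)
  })
  relation <- relation_from_sparse(tests$a00$sparse, tests$a01$sparse,
                                   tests$a10$sparse, tests$a11$sparse)
  structure(list(gene_a = gene_a, gene_b = gene_b, table = tab,
                 tests = tests, relation = relation),
            class = "implication_result")
}

#' @export
print.implication_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %s  [counts %d/%d/%d/%d, n=%d]\n",
              x$gene_a, x$gene_b, x$relation, x$table$a00, x$table$a01,
              x$table$a10, x$table$a11, x$table$n))
  invisible(x)
}

# Vectorized statistic over many pairs: a, row, col, n are equal-length
# numeric vectors. Returns list(S, p, sparse).
sparse_test_vec <- function(a, row, col, n, SThr, pThr) {
  e <- row * col / n
  ok <- n > 0 & row > 0 & col > 0
  S <- ifelse(ok, (e - a) / sqrt(e), NA_real_)
  p <- ifelse(ok, 0.5 * (a / row + a / col), NA_real_)
  list(S = S, p = p, sparse = ok & !is.na(S) & S > SThr & p < pThr)
}

#' Classify every admissible gene pair of a ternary matrix
#'
#' Computes the four quadrant counts for all unordered gene pairs at once
#' (indicator-matrix cross products, exact integer counts), applies the
#' sparse-quadrant tests, and keeps pairs whose relation is not `NONE`.
#' Each unordered pair is reported once with `gene_a < gene_b`
#' lexicographically; the converse reading follows from
#' [converse_relation()].
#'
#' @param ternary A `ternary_matrix` from [binarize_matrix()].
#' @param genes Genes to analyze; default is [dynamic_range_filter()] output.
#' @param SThr,pThr Sparsity thresholds.
#' @param keep_none Keep `NONE` pairs too (used by oracles; default `FALSE`).
#' @return Data frame of class `implication_results`: `gene_a`, `gene_b`,
#'   counts `a00..a11`, statistics `S00..S11`, error rates `p00..p11`, and
#'   `relation`; rows sorted by (`gene_a`, `gene_b`).
#' @export
all_pairs_network <- function(ternary, genes = NULL, SThr = 3, pThr = 0.1,
                              keep_none = FALSE) {
  stopifnot(inherits(ternary, "ternary_matrix"))
  if (is.null(genes)) genes <- dynamic_range_filter(ternary)
  genes <- sort(genes)
  if (length(genes) < 2L) {
    return(structure(empty_pairs_frame(), class = c("implication_results",
                                                    "data.frame")))
  }
  lab <- ternary$labels[genes, , drop = FALSE]
  L <- t(lab == 0L) * 1  # samples x genes indicators
  H <- t(lab == 2L) * 1
  A00 <- crossprod(L, L)
  A01 <- crossprod(L, H)
  A10 <- crossprod(H, L)
  A11 <- crossprod(H, H)

  ut <- upper.tri(A00)
  idx <- which(ut, arr.ind = TRUE)
  # upper.tri: row < col; order rows so output sorts by (gene_a, gene_b)
  ord <- order(idx[, "row"], idx[, "col"])
  idx <- idx[ord, , drop = FALSE]
  a00 <- A00[ut][ord]; a01 <- A01[ut][ord]
  a10 <- A10[ut][ord]; a11 <- A11[ut][ord]
  n <- a00 + a01 + a10 + a11
  row0 <- a00 + a01; row1 <- a10 + a11
  col0 <- a00 + a10; col1 <- a01 + a11

  t00 <- sparse_test_vec(a00, row0, col0, n, SThr, pThr)
  t01 <- sparse_test_vec(a01, row0, col1, n, SThr, pThr)
  t10 <- sparse_test_vec(a10, row1, col0, n, SThr, pThr)
  t11 <- sparse_test_vec(a11, row1, col1, n, SThr, pThr)
  relation <- relation_from_sparse(t00$sparse, t01$sparse,
                                   t10$sparse, t11$sparse)

  out <- data.frame(gene_a = genes[idx[, "row"]], gene_b = genes[idx[, "col"]],
                    a00 = as.integer(a00), a01 = as.integer(a01),
                    a10 = as.integer(a10), a11 = as.integer(a11),
                    S00 = t00$S, S01 = t01$S, S10 = t10$S, S11 = t11$S,
                    p00 = t00$p, p01 = t01$p, p10 = t10$p, p11 = t11$p,
                    relation = relation, stringsAsFactors = FALSE)
  if (!keep_none) out <- out[out$relation != "NONE", , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("implication_results", "data.frame"))
}

empty_pairs_frame <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             a00 = integer(0), a01 = integer(0), a10 = integer(0),
             a11 = integer(0), S00 = numeric(0), S01 = numeric(0),
             S10 = numeric(0), S11 = numeric(0), p00 = numeric(0),
             p01 = numeric(0), p10 = numeric(0), p11 = numeric(0),
             relation = character(0), stringsAsFactors = FALSE)
}

#' Look up the directed relation between two genes in a pair table
#'
#' Pairs are stored once with `gene_a < gene_b`; asking for the reversed
#' order returns the converse relation. Absent pairs are `NONE`.
#'
#' @param results An `implication_results` data frame.
#' @param a,b Gene identifiers.
#' @return A relation name.
#' @export
relation_between <- function(results, a, b) {
  if (a <= b) {
    hit <- results$relation[results$gene_a == a & results$gene_b == b]
    if (length(hit)) hit[[1L]] else "NONE"
  } else {
    hit <- results$relation[results$gene_a == b & results$gene_b == a]
    if (length(hit)) converse_relation(hit[[1L]]) else "NONE"
  }
}

#' Write an all-pairs relation table to TSV
#' @param results An `implication_results` data frame.
#' @param path Output path.
#' @export
write_pairs <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
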