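#' Fit a one-step function to a vector of expression values
#'
#' Sorts the values ascending and, over every split point
#' `k in 1..(n-1)`, minimizes the summed squared residuals of a two-level
#' step (left mean, right mean). The binarization threshold is the midpoint
#' of the two level means. Ties in the residual sum are broken toward the
#' smaller split index, making the fit deterministic.
#'
#' Samples within `margin` of the threshold are labeled intermediate and are
#' excluded from downstream pair counting; a gene is `bimodal` only if it is
#' non-constant and has at least one sample on each side of the margin.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param margin Noise margin around the threshold, in log2 units
#'   (default 0.5).
#' @return A list of class `step_fit` with fields `threshold`, `sse`,
#'   `low_mean`, `high_mean`, `margin`, `n_low`, `n_high`, `bimodal`.
#' @examples
#' fit_step(c(1, 1, 1, 5, 5, 5))$threshold  # 3
#' @export
fit_step <- function(values, margin = 0.5) {
  if (length(values) < 4L || any(!is.finite(values))) {
    stop("fit_step requires at least 4 finite values")
  }
  x <- sort(values)
  n <- length(x)
  if (x[[n]] == x[[1L]]) {
    # constant gene: no step exists; everything is intermediate
    return(structure(list(threshold = x[[1L]], sse = 0,
                          low_mean = x[[1L]], high_mean = x[[1L]],
                          margin = margin, n_low = 0L, n_high = 0L,
                          bimodal = FALSE),
                     class = "step_fit"))
  }
  # SSE(k) = total SS - n_left*mean_left^2 - n_right*mean_right^2
  cs <- cumsum(x)
  k <- seq_len(n - 1L)
  mean_left <- cs[k] / k
  mean_right <- (cs[[n]] - cs[k]) / (n - k)
  sse_k <- sum(x^2) - k * mean_left^2 - (n - k) * mean_right^2
  best <- which.min(sse_k)  # which.min returns the first minimum: smaller k
  t <- (mean_left[[best]] + mean_right[[best]]) / 2
  n_low <- sum(values < t - margin)
  n_high <- sum(values > t + margin)
  structure(list(threshold = t,
                 sse = max(sse_k[[best]], 0),
                 low_mean = mean_left[[best]],
                 high_mean = mean_right[[best]],
                 margin = margin,
                 n_low = as.integer(n_low),
                 n_high = as.integer(n_high),
                 bimodal = n_low > 0L && n_high > 0L),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step fit: t=%.4g (margin %.3g), low=%.4g high=%.4g, %d low / %d high, bimodal=%s\n",
              x$threshold, x$margin, x$low_mean, x$high_mean,
              x$n_low, x$n_high, x$bimodal))
  invisible(x)
}

#' Ternary labels for one gene given its step fit
#'
#' Label 0 (low) iff `x < t - m`; 2 (high) iff `x > t + m`; the closed
#' interval `[t - m, t + m]` maps to 1 (intermediate).
#'
#' @param values Numeric vector.
#' @param fit A `step_fit`.
#' @return Integer vector of 0/1/2 labels.
#' @export
ternary_labels <- function(values, fit) {
  lab <- rep.int(1L, length(values))
  lab[values < fit$threshold - fit$margin] <- 0L
  lab[values > fit$threshold + fit$margin] <- 2L
  lab
}

#' Binarize an expression matrix gene by gene
#'
#' Applies [fit_step()] to every row and emits the ternary label matrix plus
#' a per-gene fit table. Genes whose fit is degenerate (constant or with an
#' empty low/high arm) are flagged `bimodal = FALSE`, not dropped.
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param margin Noise margin passed to [fit_step()].
#' @return A list of class `ternary_matrix` with:
#'   * `labels`: integer matrix of 0/1/2, same dimnames as the input;
#'   * `fits`: data frame with one row per gene (`gene_id`, `threshold`,
#'     `sse`, `low_mean`, `high_mean`, `margin`, `n_low`, `n_high`,
#'     `bimodal`, `sd`).
#' @export
binarize_matrix <- function(matrix, margin = 0.5) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  fits <- vector("list", nrow(matrix))
  labels <- matrix(1L, nrow(matrix), ncol(matrix),
                   dimnames = dimnames(matrix))
  for (i in seq_len(nrow(matrix))) {
    f <- fit_step(matrix[i, ], margin = margin)
    fits[[i]] <- f
    labels[i, ] <- ternary_labels(matrix[i, ], f)
  }
  fit_df <- data.frame(
    gene_id = rownames(matrix),
    threshold = vapply(fits, `[[`, numeric(1), "threshold"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    low_mean = vapply(fits, `[[`, numeric(1), "low_mean"),
    high_mean = vapply(fits, `[[`, numeric(1), "high_mean"),
    margin = margin,
    n_low = vapply(fits, `[[`, integer(1), "n_low"),
    n_high = vapply(fits, `[[`, integer(1), "n_high"),
    bimodal = vapply(fits, `[[`, logical(1), "bimodal"),
    sd = apply(matrix, 1L, stats::sd),
    stringsAsFactors = FALSE
  )
  rownames(fit_df) <- fit_df$gene_id
  structure(list(labels = labels, fits = fit_df), class = "ternary_matrix")
}

#' @export
print.ternary_matrix <- function(x, ...) {
  cat(sprintf("ternary matrix: %d genes x %d samples, %d bimodal\n",
              nrow(x$labels), ncol(x$labels), sum(x$fits$bimodal)))
  invisible(x)
}

#' Restrict to genes with usable dynamic range
#'
#' Boolean implication analysis needs genes that actually visit both the
#' low and the high state. A gene passes iff it has at least
#' `max(min_count, ceiling(min_frac * n_samples))` samples labeled low AND
#' at least that many labeled high.
#'
#' @param ternary A `ternary_matrix`.
#' @param min_frac Minimum fraction of samples per state (default 0.05).
#' @param min_count Minimum absolute count per state (default 3).
#' @return Character vector of passing gene ids, in input row order.
#' @export
dynamic_range_filter <- function(ternary, min_frac = 0.05, min_count = 3L) {
  stopifnot(inherits(ternary, "ternary_matrix"))
  bound <- max(min_count, ceiling(min_frac * ncol(ternary$labels)))
  n_low <- rowSums(ternary$labels == 0L)
  n_high <- rowSums(ternary$labels == 2L)
  rownames(ternary$labels)[n_low >= bound & n_high >= bound]
}

#' Write ternary labels and step fits to TSV
#' @param ternary A `ternary_matrix`.
#' @param labels_path Output path for the 0/1/2 label matrix.
#' @param fits_path Optional output path for the per-gene fit table.
#' @export
write_ternary <- function(ternary, labels_path, fits_path = NULL) {
  write_expression(ternary$labels, labels_path)
  if (!is.null(fits_path)) {
    utils::write.table(ternary$fits, fits_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(labels_path)
}
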