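# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops and first-principles formulas only.

# Exhaustive one-step fit: try every split of the sorted values.
brute_fit_step <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- list(sse = Inf, k = NA, t = NA)
  for (k in 1:(n - 1)) {
    ml <- mean(x[1:k])
    mr <- mean(x[(k + 1):n])
    sse <- sum((x[1:k] - ml)^2) + sum((x[(k + 1):n] - mr)^2)
    if (sse < best$sse - 1e-12) {
      best <- list(sse = sse, k = k, t = (ml + mr) / 2)
    }
  }
  best
}

# Sample-by-sample quadrant tally.
brute_count_quadrants <- function(a, b) {
  out <- c(a00 = 0L, a01 = 0L, a10 = 0L, a11 = 0L)
  for (s in seq_along(a)) {
    if (a[s] == 1L || b[s] == 1L) next
    key <- paste0("a", as.integer(a[s] == 2L), as.integer(b[s] == 2L))
    out[key] <- out[key] + 1L
  }
  out
}

# AUC as the fraction of positive/negative pairs ranked correctly.
brute_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Ternary label vectors realizing given quadrant counts exactly.
labels_from_counts <- function(a00, a01, a10, a11, n_intermediate = 0L) {
  a <- c(rep(0L, a00 + a01), rep(2L, a10 + a11), rep(1L, n_intermediate))
  b <- c(rep(0L, a00), rep(2L, a01), rep(0L, a10), rep(2L, a11),
         rep(1L, n_intermediate))
  list(a = a, b = b)
}

# Random quadrant table with decently sized margins.
random_table <- function() {
  c(a00 = sample(0:60, 1), a01 = sample(0:60, 1),
    a10 = sample(0:60, 1), a11 = sample(0:60, 1))
}

# Recursive DFS enumerating all simple directed paths of 2..max_len nodes
# over an edge list; independent of the package's enumerator.
brute_simple_paths <- function(edges, nodes, max_len) {
  found <- list()
  extend <- function(chain) {
    if (length(chain) >= 2) found[[length(found) + 1]] <<- chain
    if (length(chain) >= max_len) return()
    nxt <- edges$to[edges$from == chain[length(chain)]]
    for (w in nxt) {
      if (!(w %in% chain)) extend(c(chain, w))
    }
  }
  for (v in nodes) extend(v)
  found
}

# A random but valid cluster network for serialization round-trips.
random_network <- function(n_clusters = 5, seed = 1) {
  set.seed(seed)
  clusters <- lapply(seq_len(n_clusters), function(i) {
    list(cluster_id = paste0("C", i),
         members = sort(paste0("g", sample(1000, sample(3:8, 1)))),
         side = sample(c("healthy", "disease", "unassigned"), 1),
         healthy_mean = round(rnorm(1), 6),
         disease_mean = round(rnorm(1), 6))
  })
  pairs <- expand.grid(from = seq_len(n_clusters), to = seq_len(n_clusters))
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[sample(nrow(pairs), min(nrow(pairs), n_clusters * 2)), ]
  edges <- data.frame(
    from = paste0("C", pairs$from), to = paste0("C", pairs$to),
    relation = sample(c("EQUIVALENT", "OPPOSITE", "LOW_LOW", "HIGH_HIGH"),
                      nrow(pairs), replace = TRUE),
    support = round(runif(nrow(pairs), 0.5, 1), 6),
    mean_S = round(runif(nrow(pairs), 3, 10), 6),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  implinet:::new_cluster_network(clusters, edges)
}

expect_network_equal <- function(a, b) {
  expect_equal(length(a$clusters), length(b$clusters))
  ids_a <- vapply(a$clusters, `[[`, character(1), "cluster_id")
  ids_b <- vapply(b$clusters, `[[`, character(1), "cluster_id")
  expect_setequal(ids_a, ids_b)
  for (cl in a$clusters) {
    other <- b$clusters[[match(cl$cluster_id, ids_b)]]
    expect_equal(cl$members, other$members)
    expect_equal(cl$side, other$side)
    expect_equal(cl$healthy_mean, other$healthy_mean, tolerance = 1e-9)
  }
  ord <- function(e) e[order(e$from, e$to), , drop = FALSE]
  ea <- ord(a$edges); eb <- ord(b$edges)
  expect_equal(ea$from, eb$from)
  expect_equal(ea$to, eb$to)
  expect_equal(ea$relation, eb$relation)
  expect_equal(ea$support, eb$support, tolerance = 1e-9)
  expect_equal(ea$mean_S, eb$mean_S, tolerance = 1e-9)
}
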