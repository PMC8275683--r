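make_results <- function(pairs) {
  # pairs: data.frame gene_a, gene_b, relation [, S columns filled with 5]
  base <- data.frame(a00 = 10L, a01 = 0L, a10 = 0L, a11 = 10L,
                     S00 = 5, S01 = 5, S10 = 5, S11 = 5,
                     p00 = 0, p01 = 0, p10 = 0, p11 = 0)
  out <- cbind(pairs, base[rep(1, nrow(pairs)), ])
  rownames(out) <- NULL
  structure(out, class = c("implication_results", "data.frame"))
}

test_that("equivalence graph has one edge per EQUIVALENT pair", {
  res <- make_results(data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    relation = c("EQUIVALENT", "EQUIVALENT", "EQUIVALENT"),
    stringsAsFactors = FALSE))
  g <- build_equivalence_graph(res)
  expect_equal(igraph::gsize(g), 3L)
  expect_equal(igraph::vcount(g), 3L)

  res$relation <- c("OPPOSITE", "LOW_LOW", "HIGH_HIGH")
  g <- build_equivalence_graph(res)
  expect_equal(igraph::gsize(g), 0L)
})

test_that("greedy clustering handles cliques exactly", {
  res <- make_results(data.frame(
    gene_a = c("g1", "g1", "g2"), gene_b = c("g2", "g3", "g3"),
    relation = "EQUIVALENT", stringsAsFactors = FALSE))
  cl <- cluster_genes(build_equivalence_graph(res))
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members, c("g1", "g2", "g3"))

  two <- expand.grid(gene_a = c("a1", "a2", "a3", "a4"),
                     gene_b = c("a1", "a2", "a3", "a4"),
                     stringsAsFactors = FALSE)
  two <- two[two$gene_a < two$gene_b, ]
  other <- expand.grid(gene_a = c("b1", "b2", "b3"),
                       gene_b = c("b1", "b2", "b3"),
                       stringsAsFactors = FALSE)
  other <- other[other$gene_a < other$gene_b, ]
  both <- rbind(two, other)
  both$relation <- "EQUIVALENT"
  cl <- cluster_genes(build_equivalence_graph(make_results(both)))
  expect_equal(length(cl), 2L)
  expect_equal(cl[[1]]$members, c("a1", "a2", "a3", "a4"))  # C1 = largest
  expect_equal(cl[[2]]$members, c("b1", "b2", "b3"))
  expect_equal(vapply(cl, `[[`, character(1), "cluster_id"), c("C1", "C2"))
})

test_that("clusters below min_cluster_size are discarded", {
  res <- make_results(data.frame(gene_a = "x", gene_b = "y",
                                 relation = "EQUIVALENT",
                                 stringsAsFactors = FALSE))
  expect_equal(length(cluster_genes(build_equivalence_graph(res),
                                    min_cluster_size = 3)), 0L)
})

test_that("planted modules are recovered exactly at 4-sigma effect", {
  spec <- synthetic_spec(
    n_samples = 200,
    modules = list(list(size = 20, side = "healthy_up", delta = 4),
                   list(size = 15, side = "disease_up", delta = 4),
                   list(size = 10, side = "disease_up", delta = 4,
                        partial = 0.5)),
    n_noise_genes = 10, seed = 19)
  sim <- generate_cohort(spec)
  tern <- binarize_matrix(sim$matrix)
  genes <- dynamic_range_filter(tern)
  res <- all_pairs_network(tern, genes)
  cl <- cluster_genes(build_equivalence_graph(res))
  got <- lapply(cl, `[[`, "members")
  planted <- lapply(sim$truth$modules, function(m) sort(m$genes))
  for (p in planted) {
    expect_true(any(vapply(got, identical, logical(1), p)),
                label = paste("module recovered:", p[1]))
  }
})

test_that("cluster network edges carry majority relation and exact support", {
  clusters <- list(
    list(cluster_id = "C1", members = c("a1", "a2"), side = "unassigned",
         healthy_mean = NA_real_, disease_mean = NA_real_),
    list(cluster_id = "C2", members = c("b1", "b2"), side = "unassigned",
         healthy_mean = NA_real_, disease_mean = NA_real_))
  cross <- expand.grid(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  cross$relation <- "OPPOSITE"
  net <- build_cluster_network(clusters, make_results(cross), 0.5)
  expect_equal(nrow(net$edges), 2L)  # both directions
  e <- net$edges[net$edges$from == "C1", ]
  expect_equal(e$relation, "OPPOSITE")
  expect_equal(e$support, 1.0)

  # 2 of 5 cross pairs LOW_LOW, rest absent (NONE): support 0.4 < 0.5
  clusters[[2]]$members <- c("b1", "b2", "b3", "b4", "b5")
  sparse_cross <- data.frame(gene_a = c("a1", "a1"),
                             gene_b = c("b1", "b2"),
                             relation = "LOW_LOW",
                             stringsAsFactors = FALSE)
  clusters[[1]]$members <- "a1"
  net <- build_cluster_network(clusters, make_results(sparse_cross), 0.5)
  expect_equal(nrow(net$edges), 0L)
  # threshold at 0.4 admits it, with the converse on the reverse edge
  net <- build_cluster_network(clusters, make_results(sparse_cross), 0.4)
  expect_equal(net$edges$relation[net$edges$from == "C1"], "LOW_LOW")
  expect_equal(net$edges$relation[net$edges$from == "C2"], "HIGH_HIGH")
  expect_equal(net$edges$support, c(0.4, 0.4))
})

test_that("edge support equals a brute-force recount on synthetic data", {
  spec <- synthetic_spec(
    n_samples = 150,
    modules = list(list(size = 6, side = "healthy_up", delta = 4),
                   list(size = 5, side = "disease_up", delta = 4)),
    n_noise_genes = 0, seed = 23)
  sim <- generate_cohort(spec)
  tern <- binarize_matrix(sim$matrix)
  res <- all_pairs_network(tern, rownames(sim$matrix))
  cl <- cluster_genes(build_equivalence_graph(res))
  net <- build_cluster_network(cl, res, 0.5)
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    from <- cl[[match(e$from, vapply(cl, `[[`, character(1),
                                     "cluster_id"))]]$members
    to <- cl[[match(e$to, vapply(cl, `[[`, character(1),
                                 "cluster_id"))]]$members
    hits <- 0L
    for (a in from) for (b in to) {
      rel <- classify_pair(tern$labels[a, ], tern$labels[b, ])$relation
      if (rel == e$relation) hits <- hits + 1L
    }
    expect_equal(e$support, hits / (length(from) * length(to)))
  }
})

test_that("orientation follows threshold-centered class means", {
  mat <- rbind(g1 = c(9, 9, 7, 7), g2 = c(10, 10, 6, 6))
  colnames(mat) <- paste0("s", 1:4)
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    class_label = c("healthy", "healthy",
                                    "disease", "disease"),
                    stringsAsFactors = FALSE)
  fits <- binarize_matrix(mat)$fits
  cl <- list(list(cluster_id = "C1", members = c("g1", "g2"),
                  side = "unassigned", healthy_mean = NA_real_,
                  disease_mean = NA_real_))
  oriented <- orient_clusters(cl, mat, ann, fits)
  expect_equal(oriented[[1]]$side, "healthy")
  expect_gt(oriented[[1]]$healthy_mean, oriented[[1]]$disease_mean)

  # flipped polarity
  oriented <- orient_clusters(cl, 16 - mat, ann, binarize_matrix(16 - mat)$fits)
  expect_equal(oriented[[1]]$side, "disease")

  # exact tie -> unassigned
  flat <- rbind(g1 = c(8, 6, 8, 6))
  colnames(flat) <- paste0("s", 1:4)
  oriented <- orient_clusters(
    list(list(cluster_id = "C1", members = "g1", side = "unassigned",
              healthy_mean = NA_real_, disease_mean = NA_real_)),
    flat, ann, binarize_matrix(flat)$fits)
  expect_equal(oriented[[1]]$side, "unassigned")

  # missing class -> unassigned
  ann1 <- ann; ann1$class_label <- "healthy"
  oriented <- orient_clusters(cl, mat, ann1, fits)
  expect_equal(oriented[[1]]$side, "unassigned")
})

test_that("clustering and network construction are deterministic", {
  spec <- synthetic_spec(seed = 44)
  sim <- generate_cohort(spec)
  tern <- binarize_matrix(sim$matrix)
  res <- all_pairs_network(tern)
  run <- function() {
    cl <- cluster_genes(build_equivalence_graph(res))
    build_cluster_network(cl, res, 0.5)
  }
  expect_identical(run(), run())
})
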