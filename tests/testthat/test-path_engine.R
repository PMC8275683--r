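toy_network <- function(edges, sides = NULL) {
  ids <- sort(unique(c(edges$from, edges$to)))
  if (is.null(sides)) sides <- stats::setNames(rep("healthy", length(ids)),
                                               ids)
  clusters <- lapply(ids, function(id) {
    list(cluster_id = id, members = paste0(id, "_g", 1:3),
         side = unname(sides[id]), healthy_mean = NA_real_,
         disease_mean = NA_real_)
  })
  edges$support <- 1; edges$mean_S <- 5
  implinet:::new_cluster_network(clusters, edges)
}

test_that("enumerate_paths lists all simple admissible chains", {
  net <- toy_network(data.frame(from = c("C1", "C2"), to = c("C2", "C3"),
                                relation = "OPPOSITE",
                                stringsAsFactors = FALSE))
  paths <- enumerate_paths(net, max_len = 5)
  keys <- vapply(paths, function(p) paste(p$clusters, collapse = ">"),
                 character(1))
  expect_equal(keys, c("C1>C2", "C1>C2>C3", "C2>C3"))
  expect_error(enumerate_paths(net, max_len = 1), "max_len")
})

test_that("cycles terminate and each simple path appears once", {
  net <- toy_network(data.frame(from = c("C1", "C2", "C3"),
                                to = c("C2", "C3", "C1"),
                                relation = "OPPOSITE",
                                stringsAsFactors = FALSE))
  paths <- enumerate_paths(net, max_len = 5)
  keys <- vapply(paths, function(p) paste(p$clusters, collapse = ">"),
                 character(1))
  expect_false(any(duplicated(keys)))
  expect_equal(length(keys), 6L)  # 3 chains of 2 nodes + 3 of 3 nodes
})

test_that("enumeration matches a brute-force DFS on a random DAG", {
  set.seed(13)
  nodes <- paste0("C", 1:8)
  pairs <- expand.grid(i = 1:8, j = 1:8)
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs <- pairs[runif(nrow(pairs)) < 0.35, ]
  edges <- data.frame(from = nodes[pairs$i], to = nodes[pairs$j],
                      relation = "OPPOSITE", stringsAsFactors = FALSE)
  net <- toy_network(edges)
  got <- vapply(enumerate_paths(net, max_len = 5),
                function(p) paste(p$clusters, collapse = ">"), character(1))
  want <- vapply(brute_simple_paths(edges, nodes, 5),
                 function(p) paste(p, collapse = ">"), character(1))
  expect_setequal(got, want)
})

test_that("EQUIVALENT edges are admissible only between same-side clusters", {
  edges <- data.frame(from = c("C1", "C2"), to = c("C2", "C3"),
                      relation = c("EQUIVALENT", "EQUIVALENT"),
                      stringsAsFactors = FALSE)
  sides <- c(C1 = "healthy", C2 = "healthy", C3 = "disease")
  paths <- enumerate_paths(toy_network(edges, sides), max_len = 3)
  keys <- vapply(paths, function(p) paste(p$clusters, collapse = ">"),
                 character(1))
  expect_equal(keys, "C1>C2")  # the cross-side equivalence is dropped
})

test_that("normalization maps thresholds to zero", {
  set.seed(2)
  m <- matrix(c(rnorm(25, 4), rnorm(25, 9)), 5, 10, byrow = FALSE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m <- rbind(m, flat = rep(3, 10))
  fits <- binarize_matrix(m)$fits
  norm <- normalize_expression(m, fits)
  expect_equal(unname(norm["flat", ]), rep(0, 10))  # constant gene -> zeros
  for (g in rownames(m)) {
    s <- stats::sd(m[g, ]); if (s == 0) s <- 1
    expect_equal(unname(norm[g, ]),
                 unname((m[g, ] - fits[g, "threshold"]) / s),
                 tolerance = 1e-12)
  }
  expect_error(normalize_expression(rbind(zz = 1:10), fits), "zz")
})

test_that("path scores are weighted cluster means", {
  norm <- rbind(a1 = c(0.8, 0), a2 = c(0.8, 0), b1 = c(-0.2, 0))
  colnames(norm) <- c("s1", "s2")
  clusters <- list(
    list(cluster_id = "C1", members = c("a1", "a2"), side = "healthy"),
    list(cluster_id = "C2", members = "b1", side = "disease"))
  path <- boolean_path(c("C1", "C2"))
  sc <- score_samples(path, norm, clusters)
  expect_equal(unname(sc["s1"]), 0.8 - (-0.2))  # w = (+1, -1)
  expect_equal(unname(sc["s2"]), 0)

  # explicit weights; zero-weight cluster is a no-op
  path3 <- boolean_path(c("C1", "C2"), weights = c(1, 0))
  expect_equal(unname(score_samples(path3, norm, clusters)["s1"]), 0.8)
  path1 <- boolean_path("C1", weights = 1)
  expect_equal(score_samples(path1, norm, clusters),
               score_samples(path3, norm, clusters))

  # linearity: scaling weights scales scores, AUC unchanged
  pw <- boolean_path(c("C1", "C2"), weights = c(2, -2))
  expect_equal(score_samples(pw, norm, clusters), 2 * sc)
  expect_error(score_samples(boolean_path("C9"), norm, clusters), "C9")
})

test_that("select_best_path prefers the discriminative path", {
  set.seed(61)
  n <- 60
  lab <- rep(c("healthy", "disease"), each = n / 2)
  signal <- ifelse(lab == "healthy", 1, -1)
  for (rep in 1:20) {
    norm <- rbind(sig = signal + rnorm(n, sd = 0.2),
                  noise = rnorm(n))
    colnames(norm) <- paste0("s", 1:n)
    ann <- data.frame(sample_id = colnames(norm), class_label = lab,
                      stringsAsFactors = FALSE)
    clusters <- list(
      list(cluster_id = "CS", members = "sig", side = "healthy"),
      list(cluster_id = "CN", members = "noise", side = "healthy"))
    paths <- list(boolean_path("CS", weights = 1),
                  boolean_path("CN", weights = 1))
    sel <- select_best_path(paths, norm, clusters, ann)
    expect_equal(sel$chosen_index, 1L)
  }
})

test_that("an exactly separating path yields p ~ 0 and single candidates win", {
  norm <- rbind(sig = c(1, 1, 1, 0, 0, 0))
  colnames(norm) <- paste0("s", 1:6)
  ann <- data.frame(sample_id = colnames(norm),
                    class_label = rep(c("healthy", "disease"), each = 3),
                    stringsAsFactors = FALSE)
  clusters <- list(list(cluster_id = "C1", members = "sig",
                        side = "healthy"))
  sel <- select_best_path(list(boolean_path("C1", weights = 1)),
                          norm, clusters, ann)
  expect_equal(sel$chosen_index, 1L)
  expect_lt(sel$table$p_value[1], 1e-10)
  ann$class_label <- "healthy"
  expect_error(select_best_path(list(boolean_path("C1", weights = 1)),
                                norm, clusters, ann), "two classes")
})

test_that("roc_auc equals the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(roc_auc(rep(5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    positive <- runif(n) < 0.5
    if (!any(positive) || all(positive)) next
    expect_equal(roc_auc(scores, positive), brute_auc(scores, positive))
  }
})

test_that("fisher_exact_2x2 matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10))
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")

  set.seed(55)
  for (rep in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("evaluate_signature agrees with direct path scoring", {
  spec <- synthetic_spec(n_samples = 100, seed = 3)
  sim <- generate_cohort(spec)
  rep <- run_pipeline(sim$matrix, sim$annotation, verbose = FALSE)
  ev <- evaluate_signature(sim$matrix, sim$annotation,
                           rep$selection$chosen,
                           clusters = rep$network$clusters)
  norm <- normalize_expression(sim$matrix, rep$ternary$fits)
  sc <- score_samples(rep$selection$chosen, norm, rep$network$clusters)
  expect_equal(ev$scores, sc)
  expect_equal(ev$auc, roc_auc(sc, sim$annotation$class_label == "healthy"))
})

test_that("label shuffles center the AUC at one half", {
  spec <- synthetic_spec(n_samples = 100, seed = 6)
  sim <- generate_cohort(spec)
  up <- sim$truth$modules[[1]]$genes
  down <- sim$truth$modules[[2]]$genes
  set.seed(17)
  aucs <- replicate(50, {
    ann <- sim$annotation
    ann$class_label <- sample(ann$class_label)
    evaluate_signature(sim$matrix, ann, list(up = up, down = down),
                       positive_label = "healthy")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("signature AUC ranks cohorts by planted effect size", {
  mods <- function(delta) list(
    list(size = 6, side = "healthy_up", delta = delta),
    list(size = 6, side = "disease_up", delta = delta))
  weak <- generate_cohort(synthetic_spec(n_samples = 120,
                                         modules = mods(1), seed = 8))
  strong <- generate_cohort(synthetic_spec(n_samples = 120,
                                           modules = mods(4), seed = 8))
  sig <- list(up = weak$truth$modules[[1]]$genes,
              down = weak$truth$modules[[2]]$genes)
  auc_weak <- evaluate_signature(weak$matrix, weak$annotation, sig,
                                 positive_label = "healthy")$auc
  auc_strong <- evaluate_signature(strong$matrix, strong$annotation, sig,
                                   positive_label = "healthy")$auc
  expect_gt(auc_strong, auc_weak)
  expect_gt(auc_strong, 0.99)

  expect_error(evaluate_signature(weak$matrix, weak$annotation,
                                  list(up = "nope1", down = "nope2")),
               "nope1")
})
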