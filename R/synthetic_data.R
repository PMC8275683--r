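#' Specify a synthetic two-class cohort with planted Boolean structure
#'
#' The generator emulates the statistical skeleton of a case/control
#' transcriptomic cohort as seen by a Boolean implication network: gene
#' modules whose members are mutually equivalent, opposite or asymmetrically
#' implicated across modules, plus non-bimodal bystander noise genes.
#' Each module gene is drawn `N(baseline +/- delta/2, noise_sd)` with the
#' sign determined by the sample's class and the module's side; `partial`
#' restricts the elevated state to a seeded subset of the up-class samples,
#' which plants asymmetric (subset) implications against full modules.
#'
#' @param n_samples Number of samples (default 200).
#' @param class_fractions Named fractions for `healthy` and `disease`
#'   (default 50/50).
#' @param modules List of module descriptors, each
#'   `list(size =, side = "healthy_up"|"disease_up", delta =, partial = 1)`
#'   with `delta` the between-state separation in noise-SD units.
#' @param n_noise_genes Bystander genes drawn `N(baseline, noise_sd)`.
#' @param noise_sd Within-state standard deviation (log2 units, default 1).
#' @param intermediate_fraction Fraction of each module gene's samples
#'   nudged into the threshold zone to exercise ternary handling
#'   (default 0.05).
#' @param baseline Log2 baseline expression (default 8).
#' @param seed Integer seed fixing all randomness.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200L,
                           class_fractions = c(healthy = 0.5, disease = 0.5),
                           modules = list(
                             list(size = 10L, side = "healthy_up", delta = 4),
                             list(size = 8L, side = "disease_up", delta = 4)),
                           n_noise_genes = 20L,
                           noise_sd = 1,
                           intermediate_fraction = 0.05,
                           baseline = 8,
                           seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 8) {
    stop("invalid spec field 'n_samples': need at least 8 samples")
  }
  if (!all(c("healthy", "disease") %in% names(class_fractions)) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop("invalid spec field 'class_fractions': need healthy+disease summing to 1")
  }
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (is.null(m$size) || m$size < 1) {
      stop("invalid spec field 'modules[[", i, "]]$size'")
    }
    if (is.null(m$side) || !m$side %in% c("healthy_up", "disease_up")) {
      stop("invalid spec field 'modules[[", i, "]]$side'")
    }
    if (is.null(m$delta) || m$delta < 0) {
      stop("invalid spec field 'modules[[", i, "]]$delta'")
    }
    if (is.null(m$partial)) modules[[i]]$partial <- 1
    else if (m$partial <= 0 || m$partial > 1) {
      stop("invalid spec field 'modules[[", i, "]]$partial'")
    }
  }
  if (n_noise_genes < 0) stop("invalid spec field 'n_noise_genes'")
  if (noise_sd <= 0) stop("invalid spec field 'noise_sd'")
  if (intermediate_fraction < 0 || intermediate_fraction > 0.5) {
    stop("invalid spec field 'intermediate_fraction'")
  }
  structure(list(n_samples = as.integer(n_samples),
                 class_fractions = class_fractions, modules = modules,
                 n_noise_genes = as.integer(n_noise_genes),
                 noise_sd = noise_sd,
                 intermediate_fraction = intermediate_fraction,
                 baseline = baseline, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Planted relation between two modules, read from their elevated-sample
# sets: equal sets -> EQUIVALENT, complementary -> OPPOSITE, nesting ->
# the matching asymmetric implication, partial overlap -> NONE.
planted_relation <- function(up_a, up_b, all_samples) {
  a <- sort(up_a); b <- sort(up_b)
  if (identical(a, b)) return("EQUIVALENT")
  if (!length(intersect(a, b))) {
    if (setequal(union(a, b), all_samples)) return("OPPOSITE")
    return("HIGH_LOW")                     # A high => B low
  }
  if (all(a %in% b)) return("HIGH_HIGH")   # A high => B high
  if (all(b %in% a)) return("LOW_LOW")     # A low  => B low
  "NONE"
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' @param spec A `synthetic_spec`.
#' @return List with:
#'   * `matrix`: expression matrix (genes x samples, log2 scale);
#'   * `annotation`: data frame `sample_id`, `class_label`;
#'   * `truth`: planted `modules` (gene memberships, sides, elevated-sample
#'     sets), `relations` (expected cross/within-module implication per
#'     module pair), and `best_path` (module ids ordered healthy side then
#'     disease side — the planted discriminative chain).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  n_h <- round(spec$class_fractions[["healthy"]] * n)
  sample_ids <- sprintf("S%03d", seq_len(n))
  class_label <- c(rep("healthy", n_h), rep("disease", n - n_h))
  annotation <- data.frame(sample_id = sample_ids, class_label = class_label,
                           stringsAsFactors = FALSE)

  module_ids <- sprintf("M%d", seq_along(spec$modules))
  genes <- character(0)
  membership <- list()
  up_sets <- list()
  rows <- list()
  for (k in seq_along(spec$modules)) {
    m <- spec$modules[[k]]
    up_class <- if (m$side == "healthy_up") "healthy" else "disease"
    up_samples <- sample_ids[class_label == up_class]
    if (m$partial < 1) {
      n_up <- max(1L, round(m$partial * length(up_samples)))
      up_samples <- sort(sample(up_samples, n_up))
    }
    up_sets[[module_ids[[k]]]] <- up_samples
    g <- sprintf("%s_g%02d", module_ids[[k]], seq_len(m$size))
    membership[[module_ids[[k]]]] <- g
    genes <- c(genes, g)
    mu <- ifelse(sample_ids %in% up_samples, m$delta / 2, -m$delta / 2)
    for (gi in g) {
      val <- spec$baseline + mu + stats::rnorm(n, sd = spec$noise_sd)
      n_mid <- round(spec$intermediate_fraction * n)
      if (n_mid > 0L && m$delta > 0) {
        mid <- sample(n, n_mid)
        val[mid] <- spec$baseline + stats::rnorm(n_mid, sd = 0.05)
      }
      rows[[gi]] <- val
    }
  }
  if (spec$n_noise_genes > 0L) {
    for (gi in sprintf("N_g%02d", seq_len(spec$n_noise_genes))) {
      rows[[gi]] <- spec$baseline + stats::rnorm(n, sd = spec$noise_sd)
      genes <- c(genes, gi)
    }
  }
  mat <- do.call(rbind, rows[genes])
  dimnames(mat) <- list(genes, sample_ids)

  informative <- module_ids[vapply(spec$modules, `[[`, numeric(1),
                                   "delta") > 0]
  relations <- list()
  if (length(informative) >= 2L) {
    combs <- utils::combn(informative, 2L)
    relations <- lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1L, i]; b <- combs[2L, i]
      list(module_a = a, module_b = b,
           relation = planted_relation(up_sets[[a]], up_sets[[b]],
                                       sample_ids))
    })
  }
  sides <- vapply(spec$modules, `[[`, character(1), "side")
  full <- vapply(spec$modules, function(m) m$partial == 1, logical(1))
  path_ids <- c(module_ids[sides == "healthy_up" & full &
                             vapply(spec$modules, `[[`, numeric(1),
                                    "delta") > 0],
                module_ids[sides == "disease_up" & full &
                             vapply(spec$modules, `[[`, numeric(1),
                                    "delta") > 0])
  truth <- list(modules = lapply(seq_along(spec$modules), function(k) {
    list(module_id = module_ids[[k]], genes = membership[[module_ids[[k]]]],
         side = spec$modules[[k]]$side, delta = spec$modules[[k]]$delta,
         partial = spec$modules[[k]]$partial,
         up_samples = up_sets[[module_ids[[k]]]])
  }), relations = relations, best_path = path_ids)
  list(matrix = mat, annotation = annotation, truth = truth)
}

#' Generate a synthetic target-vetting fixture with planted verdicts
#'
#' Builds a cohort in which an anchor gene sits in a healthy-side module,
#' success targets sit in a disease-side module whose genes are listed on
#' both continuum paths, contraindicated targets share the anchor's module
#' (anchor high => target high), and failures are split between a
#' disease-side module on only one path and unrelated noise genes placed on
#' both paths.
#'
#' @param n_success,n_failure,n_contra Planted counts (defaults 5/5/1).
#' @param n_samples,delta,noise_sd,seed Cohort parameters (defaults
#'   200/4/1/1).
#' @return List with `cohort` (as [generate_cohort()]), `anchor`, `paths`
#'   (`emt`, `fibrosis` gene lists) and `targets` (data frame `gene_id`,
#'   `planted_verdict`).
#' @export
generate_trial_fixture <- function(n_success = 5L, n_failure = 5L,
                                   n_contra = 1L, n_samples = 200L,
                                   delta = 4, noise_sd = 1, seed = 1L) {
  n_fail_path <- n_failure %/% 2L        # on one path, strong relation
  n_fail_none <- n_failure - n_fail_path # on both paths, no relation
  spec <- synthetic_spec(
    n_samples = n_samples,
    modules = list(
      list(size = max(3L, 2L + n_contra), side = "healthy_up",
           delta = delta),                         # M1: anchor + contra
      list(size = max(3L, n_success + 1L), side = "disease_up",
           delta = delta),                         # M2: both paths
      list(size = max(3L, n_fail_path + 1L), side = "disease_up",
           delta = delta)),                        # M3: EMT path only
    n_noise_genes = max(4L, n_fail_none + 2L),
    noise_sd = noise_sd, seed = seed)
  cohort <- generate_cohort(spec)
  mods <- cohort$truth$modules
  anchor <- mods[[1L]]$genes[[1L]]
  contra <- if (n_contra > 0L) mods[[1L]]$genes[1L + seq_len(n_contra)]
            else character(0)
  success <- if (n_success > 0L) mods[[2L]]$genes[seq_len(n_success)]
             else character(0)
  fail_path <- if (n_fail_path > 0L) mods[[3L]]$genes[seq_len(n_fail_path)]
               else character(0)
  noise_genes <- grep("^N_g", rownames(cohort$matrix), value = TRUE)
  fail_none <- if (n_fail_none > 0L) noise_genes[seq_len(n_fail_none)]
               else character(0)
  paths <- list(emt = c(mods[[2L]]$genes, mods[[3L]]$genes, fail_none),
                fibrosis = c(mods[[2L]]$genes, fail_none))
  targets <- data.frame(
    gene_id = c(success, fail_path, fail_none, contra),
    planted_verdict = c(rep("predicted_success", length(success)),
                        rep("predicted_failure",
                            length(fail_path) + length(fail_none)),
                        rep("contraindicated", length(contra))),
    stringsAsFactors = FALSE)
  list(cohort = cohort, anchor = anchor, paths = paths, targets = targets)
}
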