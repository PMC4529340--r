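# Cross-cohort conservation of correlated feature clusters: discovery by
# average-linkage clustering on 1 - Pearson r, validation of each cluster
# in a second cohort at the same correlation cut, size-conservation
# summary, and hypergeometric over-representation of gene lists.

#' Discover clusters of correlated features
#'
#' Features are clustered by agglomerative average linkage on the
#' distance `1 - r` (Pearson correlation across samples); the dendrogram
#' is cut at height `1 - corr_cut` and connected groups with at least
#' `min_size` members are returned, ordered by decreasing size (ties by
#' lexicographically smallest member) with deterministic ids `C1, C2, ...`.
#' Conventional thresholds are `corr_cut = 0.6`, `min_size = 10` for genes
#' and `corr_cut = 0.4`, `min_size = 5` for miRNAs.
#'
#' @param ds An [expression_dataset()] (typically after [iqr_filter()]).
#' @param corr_cut Correlation value at which the tree is cut, in (0, 1).
#' @param min_size Minimum cluster size.
#' @return List of `CorrelatedCluster` records: `id`, `members`,
#'   `seed_cohort`, `corr_cut`, `min_size`.
#' @export
discover_clusters <- function(ds, corr_cut = 0.6, min_size = 10L) {
  if (!is.numeric(corr_cut) || corr_cut <= 0 || corr_cut >= 1)
    tb_stop("corr_cut must lie in (0, 1)")
  if (ncol(ds$values) < 3) tb_stop("need at least 3 samples")
  if (nrow(ds$values) < min_size)
    tb_stop("fewer features (%d) than min_size (%d)", nrow(ds$values), min_size)
  sds <- apply(ds$values, 1, stats::sd)
  if (any(sds == 0))
    tb_stop("constant feature(s) with undefined correlation: %s",
            paste(utils::head(feature_ids(ds)[sds == 0], 5), collapse = ", "))
  groups <- cut_correlation_tree(ds$values, corr_cut)
  sizes <- table(groups)
  big <- names(sizes)[sizes >= min_size]
  clusters <- lapply(big, function(g) sort(names(groups)[groups == g]))
  if (length(clusters) == 0) return(list())
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, "", 1L))
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(i)
    structure(list(id = paste0("C", i), members = clusters[[i]],
                   seed_cohort = ds$cohort, corr_cut = corr_cut,
                   min_size = as.integer(min_size)),
              class = "CorrelatedCluster"))
}

# Average-linkage tree on 1 - Pearson r, cut at height 1 - corr_cut.
cut_correlation_tree <- function(values, corr_cut) {
  r <- stats::cor(t(values))
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, h = 1 - corr_cut)
}

#' Validate a cluster in a second cohort
#'
#' The cluster's members are re-clustered in the validation dataset with
#' the same correlation cut; `n_confirmed` is the size of the largest
#' group formed at the cut height (a group of g members implies g
#' features mutually linked above the threshold). The cluster is
#' validated when `n_confirmed >= min_confirm`.
#'
#' @param cluster A `CorrelatedCluster` from [discover_clusters()].
#' @param ds_b Validation [expression_dataset()]; members absent from it
#'   are dropped with a warning (at least 2 must be present).
#' @param min_confirm Minimum size of the largest confirmed group.
#' @return A `ClusterValidation` record: `cluster_id`, `n_confirmed`,
#'   `validated`, `min_confirm`, `n_present`.
#' @export
validate_cluster <- function(cluster, ds_b, min_confirm = 3L) {
  present <- intersect(cluster$members, feature_ids(ds_b))
  if (length(present) < length(cluster$members))
    warning(sprintf("cluster %s: %d member(s) absent from validation data",
                    cluster$id, length(cluster$members) - length(present)),
            call. = FALSE)
  if (length(present) < 2)
    tb_stop("cluster %s: fewer than 2 members present in validation data",
            cluster$id)
  sub <- ds_b$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0))
    tb_stop("constant feature(s) in validation data: %s",
            paste(present[sds == 0], collapse = ", "))
  groups <- cut_correlation_tree(sub, cluster$corr_cut)
  n_confirmed <- max(table(groups))
  structure(list(cluster_id = cluster$id,
                 n_confirmed = as.integer(n_confirmed),
                 validated = n_confirmed >= min_confirm,
                 min_confirm = as.integer(min_confirm),
                 n_present = length(present)),
            class = "ClusterValidation")
}

#' Summarise cluster conservation across cohorts
#'
#' @param clusters List of `CorrelatedCluster` records.
#' @param validations Matching list of `ClusterValidation` records.
#' @return List with `n_discovered`, `n_validated`, `fraction`, and
#'   `size_pearson_r`, the Pearson correlation between seed-cluster size
#'   and confirmed size across validated clusters (`NA` when fewer than 3
#'   validated pairs).
#' @export
conservation_summary <- function(clusters, validations) {
  if (length(clusters) == 0) tb_stop("no clusters discovered; fraction undefined")
  if (length(clusters) != length(validations))
    tb_stop("clusters and validations must match")
  val <- vapply(validations, `[[`, TRUE, "validated")
  sizes <- lengths(lapply(clusters, `[[`, "members"))
  conf <- vapply(validations, `[[`, 1L, "n_confirmed")
  r <- if (sum(val) >= 3)
    stats::cor(sizes[val], conf[val]) else NA_real_
  list(n_discovered = length(clusters), n_validated = sum(val),
       fraction = sum(val) / length(clusters), size_pearson_r = r)
}

#' Hypergeometric over-representation of a gene set in a cluster
#'
#' Upper-tail probability (including the observed overlap) of drawing at
#' least `k` set members when `n` cluster members are sampled without
#' replacement from a universe of `N` features containing `K` set
#' members. The universe should be the feature population the clusters
#' were discovered in.
#'
#' @param cluster_members Character vector of cluster features.
#' @param gene_set Character vector (or gene-set record) of set members.
#' @param universe Character vector of all candidate features.
#' @return List with `k`, `n`, `K`, `N`, `p`.
#' @export
hypergeometric_enrichment <- function(cluster_members, gene_set, universe) {
  if (length(universe) == 0) tb_stop("empty universe")
  if (is.list(gene_set)) gene_set <- gene_set$members
  cl <- intersect(unique(cluster_members), universe)
  gs <- intersect(unique(gene_set), universe)
  k <- length(intersect(cl, gs))
  n <- length(cl); K <- length(gs); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = p)
}

#' Enrichment of many gene sets across many clusters
#'
#' @param clusters List of `CorrelatedCluster` records.
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param universe Feature universe (defaults handled by caller).
#' @param p_cut Nominal significance rule (reported alongside BH-adjusted p).
#' @return data.frame with one row per cluster x set.
#' @export
enrichment_table <- function(clusters, gene_sets, universe, p_cut = 0.01) {
  rows <- lapply(clusters, function(cl)
    lapply(names(gene_sets), function(gs) {
      e <- hypergeometric_enrichment(cl$members, gene_sets[[gs]], universe)
      data.frame(cluster_id = cl$id, gene_set = gs, k = e$k, n = e$n,
                 K = e$K, N = e$N, p = e$p, stringsAsFactors = FALSE)
    }))
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_cut
  out
}

#' Bidirectional cluster conservation report
#'
#' Runs discovery and validation A -> B and B -> A (and, when a third
#' dataset is given, from it towards both A and B) and returns one
#' conservation summary per direction.
#'
#' @param ds_a,ds_b Preprocessed [expression_dataset()] objects.
#' @param corr_cut,min_size,min_confirm Discovery/validation parameters.
#' @param ds_c Optional third dataset used as an additional seed.
#' @return Named list of direction reports, each holding `clusters`,
#'   `validations` and `summary`.
#' @export
bidirectional_conservation <- function(ds_a, ds_b, corr_cut = 0.6,
                                       min_size = 10L, min_confirm = 3L,
                                       ds_c = NULL) {
  run_dir <- function(seed, target) {
    cl <- discover_clusters(seed, corr_cut = corr_cut, min_size = min_size)
    if (length(cl) == 0)
      return(list(clusters = cl, validations = list(), summary = NULL))
    va <- lapply(cl, validate_cluster, ds_b = target, min_confirm = min_confirm)
    list(clusters = cl, validations = va,
         summary = conservation_summary(cl, va))
  }
  out <- list(a_to_b = run_dir(ds_a, ds_b), b_to_a = run_dir(ds_b, ds_a))
  if (!is.null(ds_c)) {
    out$c_to_a <- run_dir(ds_c, ds_a)
    out$c_to_b <- run_dir(ds_c, ds_b)
  }
  out
}
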