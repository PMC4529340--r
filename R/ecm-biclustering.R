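# Large Average Submatrices (LAS) biclustering over ECM-related genes.
# The search alternately optimises the row set given the columns and the
# column set given the rows, maximising a Bonferroni-style significance
# score for the average of a k x l submatrix of a standardized m x n
# matrix; found biclusters are labelled ECM1/ECM3 by hypergeometric
# overlap with marker seed lists, and run-to-run stability is summarised
# by pairwise Jaccard of the recovered gene sets.

#' LAS significance score of a submatrix average
#'
#' For a k x l submatrix with standardized average `tau` inside an m x n
#' matrix, the score is
#' `-[log C(m,k) + log C(n,l) + log Phi(-tau * sqrt(k*l))]`,
#' computed in log space (log-gamma binomials; the Gaussian tail uses the
#' asymptotic expansion for large arguments via `pnorm(log.p = TRUE)`).
#' Larger scores mean submatrices less likely under a standard normal
#' null. Strictly increasing in `tau` for fixed dimensions.
#'
#' @param k,l Submatrix dimensions (1 <= k <= m, 1 <= l <= n).
#' @param tau Submatrix average of the standardized matrix.
#' @param m,n Matrix dimensions.
#' @return Numeric score (vectorised over `k`/`tau`).
#' @export
las_score <- function(k, l, tau, m, n) {
  if (any(k < 1) || any(k > m) || any(l < 1) || any(l > n))
    tb_stop("submatrix dimensions out of range (k in [1,%d], l in [1,%d])", m, n)
  -(lchoose(m, k) + lchoose(n, l) +
      stats::pnorm(-tau * sqrt(k * l), log.p = TRUE))
}

#' Greedy LAS search for large-average biclusters
#'
#' Each restart initialises a random column subset and alternates: given
#' the columns, rows are sorted by their mean over those columns and the
#' prefix size maximising [las_score()] is kept; given the rows, the
#' symmetric step selects columns. Iteration stops at a fixed point. The
#' best bicluster over all restarts is recorded, its mean is subtracted
#' from the submatrix, and the search repeats for further biclusters,
#' stopping early when the best score drops below `score_floor` (the
#' score of a single cell at tau = 3 by default).
#'
#' @param x Standardized numeric matrix (overall mean approximately 0,
#'   sd approximately 1); all values must be finite.
#' @param n_biclusters Maximum number of biclusters to extract.
#' @param n_restarts Random restarts per bicluster.
#' @param seed Integer seed; results are deterministic given it.
#' @param score_floor Early-stopping score threshold.
#' @return List of `Bicluster` records: `rows`, `cols`, `tau`, `score`.
#' @export
las_search <- function(x, n_biclusters = 5L, n_restarts = 10L, seed = 1L,
                       score_floor = las_score(1, 1, 3, nrow(x), ncol(x))) {
  if (!all(is.finite(x))) tb_stop("matrix contains non-finite values")
  if (n_restarts < 1) tb_stop("n_restarts must be >= 1")
  withr::with_seed(seed, las_search_impl(x, n_biclusters, n_restarts,
                                         score_floor))
}

las_search_impl <- function(x, n_biclusters, n_restarts, score_floor) {
  m <- nrow(x); n <- ncol(x)
  out <- list()
  for (b in seq_len(n_biclusters)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cand <- las_fixed_point(x, sample.int(n, max(2L, rbinom_size(n))))
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    if (is.null(best) || best$score < score_floor) break
    out[[b]] <- structure(
      list(rows = sort(rownames(x)[best$rows]),
           cols = sort(colnames(x)[best$cols]),
           tau = best$tau, score = best$score),
      class = "Bicluster")
    x[best$rows, best$cols] <- x[best$rows, best$cols] - best$tau
  }
  out
}

rbinom_size <- function(n) stats::rbinom(1, n, 0.5)

# Alternate row/column selection until the (rows, cols) pair repeats.
las_fixed_point <- function(x, cols, max_iter = 50L) {
  m <- nrow(x); n <- ncol(x)
  rows <- integer(0)
  for (it in seq_len(max_iter)) {
    prev_rows <- rows; prev_cols <- cols
    # best row prefix given the columns
    rm <- rowMeans(x[, cols, drop = FALSE])
    ord <- order(rm, decreasing = TRUE)
    taus <- cumsum(rm[ord]) / seq_len(m)
    sc <- las_score(seq_len(m), length(cols), taus, m, n)
    k <- which.max(sc)
    rows <- ord[seq_len(k)]
    # best column prefix given the rows
    cm <- colMeans(x[rows, , drop = FALSE])
    ordc <- order(cm, decreasing = TRUE)
    tausc <- cumsum(cm[ordc]) / seq_len(n)
    scc <- las_score(length(rows), seq_len(n), tausc, m, n)
    l <- which.max(scc)
    cols <- ordc[seq_len(l)]
    if (setequal(rows, prev_rows) && setequal(cols, prev_cols)) break
  }
  tau <- mean(x[rows, cols])
  list(rows = rows, cols = cols, tau = tau,
       score = las_score(length(rows), length(cols), tau, m, n))
}

# Row-median-center then scale to overall unit variance: removes per-gene
# baseline offsets so the score's standard normal null is sensible.
standardize_for_las <- function(values) {
  v <- sweep(values, 1, apply(values, 1, stats::median))
  v <- v - mean(v)
  v / stats::sd(as.vector(v))
}

#' Identify and label ECM biclusters
#'
#' Restricts the dataset to the ECM universe, standardizes (row-median
#' centering, then global unit variance), runs [las_search()], and labels
#' each bicluster `ECM1` or `ECM3` when its hypergeometric overlap with
#' the corresponding seed list is below `p_cut` (the smaller p wins when
#' both match). Samples in a labelled bicluster's column set receive that
#' ECM class; biclusters found by an earlier (higher-score) extraction
#' take precedence.
#'
#' @param ds An [expression_dataset()].
#' @param ecm_universe Character vector (or gene-set record) of ECM genes.
#' @param ecm1_seed,ecm3_seed Seed gene lists for labelling.
#' @param n_biclusters,n_restarts,seed Passed to [las_search()].
#' @param p_cut Labelling significance threshold.
#' @return List with `biclusters` (each with an extra `label`),
#'   `sample_class` (named vector: ECM1, ECM3 or unassigned) and
#'   `identified` (logical: was any bicluster labelled).
#' @export
identify_ecm_clusters <- function(ds, ecm_universe,
                                  ecm1_seed = ecm_seed_genes("ecm1"),
                                  ecm3_seed = ecm_seed_genes("ecm3"),
                                  n_biclusters = 5L, n_restarts = 10L,
                                  seed = 1L, p_cut = 0.01) {
  if (is.list(ecm_universe)) ecm_universe <- ecm_universe$members
  if (is.list(ecm1_seed)) ecm1_seed <- ecm1_seed$members
  if (is.list(ecm3_seed)) ecm3_seed <- ecm3_seed$members
  univ <- intersect(ecm_universe, feature_ids(ds))
  if (length(univ) < 4) tb_stop("too few ECM universe genes present (%d)",
                                length(univ))
  if (!any(ecm1_seed %in% univ) || !any(ecm3_seed %in% univ))
    tb_stop("ECM seed genes absent from the universe present in the data")
  z <- standardize_for_las(ds$values[univ, , drop = FALSE])
  bcs <- las_search(z, n_biclusters = n_biclusters, n_restarts = n_restarts,
                    seed = seed)
  sample_class <- stats::setNames(rep("unassigned", ncol(z)), colnames(z))
  seen <- character(0)
  bcs <- lapply(bcs, function(bc) {
    p1 <- hypergeometric_enrichment(bc$rows, ecm1_seed, univ)$p
    p3 <- hypergeometric_enrichment(bc$rows, ecm3_seed, univ)$p
    bc$label <- if (min(p1, p3) >= p_cut) "none"
    else if (p3 < p1) "ECM3" else "ECM1"
    bc$label_p <- min(p1, p3)
    bc
  })
  for (bc in bcs) {
    if (bc$label %in% c("ECM1", "ECM3") && !(bc$label %in% seen)) {
      free <- bc$cols[sample_class[bc$cols] == "unassigned"]
      sample_class[free] <- bc$label
      seen <- c(seen, bc$label)
    }
  }
  identified <- length(seen) > 0
  if (!identified) tb_log("no bicluster matched either ECM seed list: not identified",
                          level = "WARN")
  list(biclusters = bcs, sample_class = sample_class, identified = identified)
}

#' Run-to-run stability of an ECM cluster
#'
#' Repeats [identify_ecm_clusters()] with distinct seeds and summarises
#' the pairwise Jaccard similarity of the target cluster's gene sets. The
#' cluster is flagged unstable when it is identified in no more than half
#' of the runs or when the mean pairwise Jaccard falls below
#' `stability_floor`.
#'
#' @param ds,ecm_universe,ecm1_seed,ecm3_seed,n_biclusters,n_restarts,p_cut
#'   As in [identify_ecm_clusters()].
#' @param target `"ECM3"` or `"ECM1"`.
#' @param n_runs Number of runs (>= 2).
#' @param seeds Integer vector of length `n_runs` (default `1:n_runs`).
#' @return A `StabilityReport`: `n_runs`, `n_identified`, `jaccard`
#'   (matrix across identified runs, diagonal 1), `mean_jaccard`,
#'   `stable`.
#' @export
stability_analysis <- function(ds, ecm_universe,
                               ecm1_seed = ecm_seed_genes("ecm1"),
                               ecm3_seed = ecm_seed_genes("ecm3"),
                               target = "ECM3", n_runs = 20L,
                               seeds = seq_len(n_runs),
                               n_biclusters = 5L, n_restarts = 10L,
                               p_cut = 0.01, stability_floor = 0.6) {
  if (n_runs < 2) tb_stop("n_runs must be >= 2")
  if (length(seeds) != n_runs) tb_stop("need one seed per run")
  gene_sets <- lapply(seeds, function(s) {
    res <- identify_ecm_clusters(ds, ecm_universe, ecm1_seed, ecm3_seed,
                                 n_biclusters = n_biclusters,
                                 n_restarts = n_restarts, seed = s,
                                 p_cut = p_cut)
    labs <- vapply(res$biclusters, `[[`, "", "label")
    if (target %in% labs) res$biclusters[[which(labs == target)[1]]]$rows
    else NULL
  })
  found <- !vapply(gene_sets, is.null, TRUE)
  sets <- gene_sets[found]
  jac <- matrix(NA_real_, length(sets), length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    jac[i, j] <- jaccard(sets[[i]], sets[[j]])
  mean_j <- if (length(sets) >= 2) mean(jac[lower.tri(jac)]) else NA_real_
  structure(list(n_runs = n_runs, n_identified = sum(found), jaccard = jac,
                 mean_jaccard = mean_j,
                 stable = sum(found) > n_runs / 2 &&
                   !is.na(mean_j) && mean_j >= stability_floor),
            class = "StabilityReport")
}
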