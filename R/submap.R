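# Subclass mapping: do subtypes found independently in two datasets
# correspond? For each subtype pair the marker genes of one dataset's
# subtype (top signal-to-noise features vs the rest) are tested for
# enrichment at the top of the other dataset's subtype-vs-rest ranking
# with a weighted Kolmogorov-Smirnov statistic and a gene-set permutation
# null; forward and reverse p-values are combined by Fisher's method and
# the cell matrix is FDR-adjusted.

#' Signal-to-noise marker ranking for one subclass
#'
#' Per feature, `(mu_in - mu_out) / (sd_in + sd_out)` with each standard
#' deviation floored at `sd_floor_frac * |mu|` of its group (the usual
#' GenePattern-style variance floor); features are returned sorted by
#' decreasing score.
#'
#' @param ds An [expression_dataset()] or a numeric feature x sample matrix.
#' @param labels Character vector of subclass labels per sample.
#' @param subclass The subclass whose markers are ranked (>= 3 samples in
#'   and out of the class).
#' @param sd_floor_frac Standard-deviation floor as a fraction of the
#'   group mean magnitude.
#' @return data.frame with `feature` and `score`, sorted descending.
#' @export
snr_marker_ranking <- function(ds, labels, subclass, sd_floor_frac = 0.2) {
  v <- if (inherits(ds, "ExpressionDataset")) ds$values else ds
  if (length(labels) != ncol(v)) tb_stop("labels must cover every sample")
  inn <- labels == subclass
  if (sum(inn) < 3 || sum(!inn) < 3)
    tb_stop("subclass '%s' needs >= 3 samples in and out of the class", subclass)
  score <- snr_scores(v, inn, sd_floor_frac)
  ord <- order(score, decreasing = TRUE)
  data.frame(feature = rownames(v)[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

# Vectorised signal-to-noise scores for one in/out split. With an empty
# out-group (a dataset holding a single subclass) the ranking degrades to
# centered in-class means.
snr_scores <- function(v, inn, sd_floor_frac = 0.2) {
  ni <- sum(inn); no <- sum(!inn)
  if (no == 0) {
    mi <- rowMeans(v)
    return(mi - mean(mi))
  }
  vi <- v[, inn, drop = FALSE]; vo <- v[, !inn, drop = FALSE]
  mi <- rowMeans(vi); mo <- rowMeans(vo)
  si <- sqrt(pmax(rowSums(vi * vi) - ni * mi^2, 0) / (ni - 1))
  so <- sqrt(pmax(rowSums(vo * vo) - no * mo^2, 0) / (no - 1))
  si <- pmax(si, sd_floor_frac * abs(mi))
  so <- pmax(so, sd_floor_frac * abs(mo))
  den <- si + so
  ifelse(den > 0, (mi - mo) / den, 0)
}

# Enrichment score from a score vector sorted decreasingly, given marker
# positions in that order (fast path used by submap's permutation loop).
es_from_sorted <- function(scores_sorted, pos) {
  N <- length(scores_sorted); Nh <- length(pos)
  pos <- sort(pos)
  w <- abs(scores_sorted[pos])
  if (sum(w) == 0) w <- rep(1, Nh)
  max(cumsum(w) / sum(w) - (pos - seq_len(Nh)) / (N - Nh))
}

# Weighted KS enrichment score of a marker set at the top of a ranked
# list: hits advance the running sum by |score| / sum(|score| over hits),
# misses retreat by 1 / (N - Nh); ES is the maximum deviation.
enrichment_score <- function(ranked, markers) {
  pos <- match(markers, ranked$feature)
  if (anyNA(pos)) tb_stop("marker set contains features absent from the ranking")
  pos <- sort(pos)
  N <- nrow(ranked); Nh <- length(pos)
  if (Nh == 0) tb_stop("empty marker set")
  if (Nh >= N) tb_stop("marker set must be smaller than the ranking")
  w <- abs(ranked$score[pos])
  if (sum(w) == 0) w <- rep(1, Nh)
  cum_hit <- cumsum(w) / sum(w)
  miss_before <- (pos - seq_len(Nh)) / (N - Nh)
  max(cum_hit - miss_before)
}

#' Permutation p-value for marker-set enrichment in a ranked list
#'
#' The observed [weighted KS enrichment score][snr_marker_ranking] is
#' compared to scores of random gene sets of the same size drawn from the
#' ranked features: `p = (1 + #{perm ES >= obs}) / (1 + n_perm)`. With
#' `exact = TRUE` all possible sets are enumerated instead (only sensible
#' for tiny rankings) and `p = #{ES >= obs} / #sets`.
#'
#' @param ranked data.frame from [snr_marker_ranking()] (or any ranking
#'   with `feature` and `score`, sorted descending).
#' @param markers Character vector of marker features (subset of the
#'   ranking).
#' @param n_perm Number of random sets (>= 100 recommended).
#' @param seed Integer seed.
#' @param exact Enumerate all sets instead of sampling.
#' @return List with `es` and `p`.
#' @export
enrichment_pvalue <- function(ranked, markers, n_perm = 500L, seed = 1L,
                              exact = FALSE) {
  obs <- enrichment_score(ranked, markers)
  N <- nrow(ranked); Nh <- length(unique(markers))
  if (exact) {
    sets <- utils::combn(ranked$feature, Nh, simplify = FALSE)
    es <- vapply(sets, function(s) enrichment_score(ranked, s), 0)
    return(list(es = obs, p = mean(es >= obs - 1e-12)))
  }
  p <- withr::with_seed(seed, {
    hits <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(ranked$feature, Nh))
    }, 0)
    (1 + sum(hits >= obs)) / (1 + n_perm)
  })
  list(es = obs, p = p)
}

#' Subclass mapping between two labelled datasets
#'
#' For every subtype pair (i of dataset A, j of dataset B): the top
#' `marker_n` signal-to-noise markers of A_i are tested for enrichment in
#' the B_j-vs-rest ranking (forward p) and vice versa (reverse p); the
#' cell's nominal p is the larger of the two (mutual enrichment is
#' required for a correspondence) and the full cell matrix is
#' Benjamini-Hochberg adjusted. Deterministic for a fixed seed.
#'
#' With `null = "sample"` (the default) the permutation null reshuffles
#' the subclass labels of the ranked dataset and recomputes the ranking,
#' so coherent transcriptional programs shared by several subclasses
#' (ER, proliferation) inflate the null exactly as they inflate the
#' observed score; this is what makes the association matrix specific to
#' matching subclasses. `null = "geneset"` instead permutes marker-set
#' membership (the plain enrichment null of [enrichment_pvalue()]),
#' provided for sensitivity analysis.
#'
#' @param ds_a,ds_b [expression_dataset()] objects.
#' @param labels_a,labels_b Subclass labels per sample (samples labelled
#'   NA or `Unclassified` are dropped).
#' @param marker_n Markers per subclass.
#' @param n_perm Permutations per enrichment test.
#' @param seed Integer seed.
#' @param min_common Minimum number of shared features required.
#' @param size_floor Minimum samples per subclass.
#' @param null Permutation null: `"sample"` (label permutation) or
#'   `"geneset"` (marker-set permutation).
#' @return An `AssociationMatrix`: `fdr` and `nominal_p` (subtypes of A x
#'   subtypes of B), `p_forward`, `p_reverse`, `n_permutations`, `seed`.
#' @export
submap <- function(ds_a, labels_a, ds_b, labels_b, marker_n = 50L,
                   n_perm = 200L, seed = 1L, min_common = 500L,
                   size_floor = 3L, null = c("sample", "geneset")) {
  null <- match.arg(null)
  common <- intersect(feature_ids(ds_a), feature_ids(ds_b))
  if (length(common) == 0) tb_stop("no features shared between the datasets")
  if (length(common) < min_common)
    tb_stop("only %d shared features (< min_common = %d)", length(common),
            min_common)
  keep <- function(l) !is.na(l) & !(l %in% c("Unclassified", "Undetermined"))
  ka <- keep(labels_a); kb <- keep(labels_b)
  va <- ds_a$values[common, ka, drop = FALSE]; la <- labels_a[ka]
  vb <- ds_b$values[common, kb, drop = FALSE]; lb <- labels_b[kb]
  subs_a <- sort(unique(la)); subs_b <- sort(unique(lb))
  if (any(table(la) < size_floor) || any(table(lb) < size_floor))
    tb_stop("every subclass needs >= %d samples", size_floor)

  rank_subclasses <- function(v, labels, subs) {
    out <- lapply(subs, function(s) {
      sc <- snr_scores(v, labels == s)
      ord <- order(sc, decreasing = TRUE)
      list(order = ord, scores = sc[ord])
    })
    names(out) <- subs
    out
  }
  rank_a <- rank_subclasses(va, la, subs_a)
  rank_b <- rank_subclasses(vb, lb, subs_b)
  feat_idx <- stats::setNames(seq_along(common), common)
  marker_idx <- function(rk) rk$order[seq_len(min(marker_n, length(rk$order)))]
  mark_a <- lapply(rank_a, marker_idx)   # row indices into `common`
  mark_b <- lapply(rank_b, marker_idx)
  es_cell <- function(rk, markers) {
    pos <- match(markers, rk$order)
    es_from_sorted(rk$scores, pos)
  }
  obs_f <- outer(subs_a, subs_b, Vectorize(function(i, j)
    es_cell(rank_b[[j]], mark_a[[i]])))
  obs_r <- outer(subs_a, subs_b, Vectorize(function(i, j)
    es_cell(rank_a[[i]], mark_b[[j]])))
  dimnames(obs_f) <- dimnames(obs_r) <- list(subs_a, subs_b)

  pf <- pr <- matrix(NA_real_, length(subs_a), length(subs_b),
                     dimnames = list(subs_a, subs_b))
  if (null == "sample") {
    withr::with_seed(seed, {
      ge_f <- ge_r <- matrix(0L, length(subs_a), length(subs_b))
      for (r in seq_len(n_perm)) {
        prk_b <- rank_subclasses(vb, sample(lb), subs_b)
        prk_a <- rank_subclasses(va, sample(la), subs_a)
        for (i in seq_along(subs_a)) for (j in seq_along(subs_b)) {
          if (es_cell(prk_b[[j]], mark_a[[i]]) >= obs_f[i, j])
            ge_f[i, j] <- ge_f[i, j] + 1L
          if (es_cell(prk_a[[i]], mark_b[[j]]) >= obs_r[i, j])
            ge_r[i, j] <- ge_r[i, j] + 1L
        }
      }
      pf[] <- (1 + ge_f) / (1 + n_perm)
      pr[] <- (1 + ge_r) / (1 + n_perm)
    })
  } else {
    withr::with_seed(seed, {
      for (i in seq_along(subs_a)) for (j in seq_along(subs_b)) {
        null_f <- vapply(seq_len(n_perm), function(r)
          es_from_sorted(rank_b[[j]]$scores,
                         sample.int(length(common), length(mark_a[[i]]))), 0)
        null_r <- vapply(seq_len(n_perm), function(r)
          es_from_sorted(rank_a[[i]]$scores,
                         sample.int(length(common), length(mark_b[[j]]))), 0)
        pf[i, j] <- (1 + sum(null_f >= obs_f[i, j])) / (1 + n_perm)
        pr[i, j] <- (1 + sum(null_r >= obs_r[i, j])) / (1 + n_perm)
      }
    })
  }
  # Mutual-significance rule: a correspondence requires marker enrichment
  # in BOTH directions, so the cell p is the larger of the two (valid
  # under the strong forward/reverse dependence of the permutation null).
  nominal <- pmax(pf, pr)
  fdr <- matrix(stats::p.adjust(nominal, method = "BH"), nrow(nominal),
                dimnames = dimnames(nominal))
  structure(list(fdr = fdr, nominal_p = nominal, p_forward = pf,
                 p_reverse = pr, es_forward = obs_f, es_reverse = obs_r,
                 n_permutations = n_perm, seed = seed, null = null),
            class = "AssociationMatrix")
}

#' Plot an association matrix as a shaded grid
#'
#' @param x An `AssociationMatrix` from [submap()].
#' @param alpha Significance level annotated on the cells.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot_association_matrix <- function(x, alpha = 0.05, ...) {
  f <- x$fdr
  graphics::image(seq_len(ncol(f)), seq_len(nrow(f)), t(1 - f)[, rev(seq_len(nrow(f))), drop = FALSE],
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(f)), colnames(f))
  graphics::axis(2, seq_len(nrow(f)), rev(rownames(f)), las = 2)
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f)))
    if (f[i, j] < alpha)
      graphics::text(j, nrow(f) - i + 1, sprintf("%.3f", f[i, j]), col = "red")
  invisible(x)
}
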