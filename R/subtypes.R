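# Molecular subtyping: bimodal marker thresholds, PAM50-gene hierarchical
# subtyping with centroid-majority labelling, claudin-low rescue of
# unclassified samples, Carey IHC surrogate classes, frequency tables, and
# PCA-based group-separation summaries.

#' Threshold a marker gene at the minimum of its bimodal density
#'
#' A Gaussian kernel density estimate is computed on a 512-point grid
#' spanning the data range extended by one bandwidth on each side.
#' Turning points are sign changes of successive density differences; the
#' threshold is the deepest interior minimum between the two highest
#' maxima. Unimodal densities raise an error of class
#' `transbrca_non_bimodal`.
#'
#' @param values Numeric vector of per-sample expression for one gene
#'   (at least 20 values, not constant).
#' @param bw Bandwidth rule or value passed to [stats::density()].
#' @return List with `threshold`, `density_minima` (all interior minima),
#'   `density_maxima`, and `bandwidth`.
#' @export
bimodal_threshold <- function(values, bw = "nrd0") {
  values <- as.numeric(values)
  if (length(values) < 20) tb_stop("need at least 20 values")
  if (stats::sd(values) == 0) tb_stop("constant values; no density to threshold")
  bwv <- if (is.character(bw)) stats::bw.nrd0(values) else bw
  d <- stats::density(values, bw = bwv, n = 512,
                      from = min(values) - bwv, to = max(values) + bwv)
  dy <- diff(d$y)
  s <- sign(dy)
  # indices (on the grid) where the slope changes sign
  turn <- which(s[-1] != s[-length(s)] & s[-length(s)] != 0) + 1L
  maxima <- turn[d$y[turn] >= d$y[turn - 1] & d$y[turn] >= d$y[turn + 1]]
  minima <- turn[d$y[turn] <= d$y[turn - 1] & d$y[turn] <= d$y[turn + 1]]
  if (length(maxima) < 2 || length(minima) == 0)
    stop(structure(class = c("transbrca_non_bimodal", "error", "condition"),
                   list(message = "density is not bimodal (no interior minimum)",
                        call = NULL)))
  top2 <- sort(maxima[order(-d$y[maxima])][1:2])
  between <- minima[minima > top2[1] & minima < top2[2]]
  if (length(between) == 0)
    stop(structure(class = c("transbrca_non_bimodal", "error", "condition"),
                   list(message = "no density minimum between the two dominant modes",
                        call = NULL)))
  pit <- between[which.min(d$y[between])]
  list(threshold = d$x[pit],
       density_minima = d$x[minima],
       density_maxima = d$x[maxima],
       bandwidth = bwv)
}

#' Call per-sample marker status from a bimodal expression distribution
#'
#' @param ds An [expression_dataset()].
#' @param gene Marker gene id (e.g. `"ESR1"` or `"ERBB2"`).
#' @param bw Bandwidth rule passed to [bimodal_threshold()].
#' @return Named logical vector (TRUE = positive, expression above the
#'   threshold) with the threshold attached as attribute `"threshold"`.
#' @export
classify_marker_status <- function(ds, gene, bw = "nrd0") {
  if (!gene %in% feature_ids(ds)) tb_stop("gene %s not in dataset", gene)
  x <- ds$values[gene, ]
  th <- bimodal_threshold(x, bw = bw)
  structure(x > th$threshold, threshold = th$threshold)
}

#' Assign intrinsic subtypes by hierarchical clustering on the PAM50-like panel
#'
#' Samples are clustered with average linkage and Euclidean distance on
#' the row-median-centered panel expression; the dendrogram is cut into
#' `k` groups. Each group is labelled by the majority of per-sample
#' nearest-centroid calls (Spearman correlation against the supplied
#' centroids); groups smaller than `min_group` or whose majority
#' correlation falls below `min_cor` remain `Unclassified`.
#'
#' @param ds An [expression_dataset()].
#' @param panel Character vector of panel genes (or gene-set record);
#'   at least `coverage_floor` of them must be present.
#' @param centroids Numeric matrix, panel genes x subtype, defaults to the
#'   bundled synthetic centroids [pam50_centroids()].
#' @param k Number of dendrogram groups.
#' @param min_group Minimum group size for a subtype label.
#' @param min_cor Minimum majority median centroid correlation.
#' @param coverage_floor Minimum fraction of panel genes present.
#' @return data.frame with `sample_id`, `intrinsic` (LumA, LumB, ERBB2,
#'   Basal or Unclassified) and `centroid_cor`.
#' @export
assign_intrinsic_subtypes <- function(ds, panel = pam50_panel()$gene,
                                      centroids = pam50_centroids(),
                                      k = 6L, min_group = 3L, min_cor = 0.1,
                                      coverage_floor = 0.6) {
  if (is.list(panel)) panel <- panel$members
  present <- intersect(panel, feature_ids(ds))
  if (length(present) < coverage_floor * length(panel))
    tb_stop("only %d of %d panel genes present (floor %.0f%%); missing: %s",
            length(present), length(panel), 100 * coverage_floor,
            paste(utils::head(setdiff(panel, present), 10), collapse = ", "))
  x <- ds$values[present, , drop = FALSE]
  x <- sweep(x, 1, apply(x, 1, stats::median))
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "average")
  groups <- stats::cutree(hc, k = min(k, ncol(x)))
  cen <- centroids[intersect(present, rownames(centroids)), , drop = FALSE]
  xs <- x[rownames(cen), , drop = FALSE]
  cors <- stats::cor(xs, cen, method = "spearman")
  best <- colnames(cors)[max.col(cors, ties.method = "first")]
  best_cor <- cors[cbind(seq_len(nrow(cors)), max.col(cors, ties.method = "first"))]
  intrinsic <- rep("Unclassified", ncol(x))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_group) next
    tab <- sort(table(best[idx]), decreasing = TRUE)
    major <- names(tab)[1]
    med <- stats::median(cors[idx, major])
    if (med >= min_cor) intrinsic[idx] <- major
  }
  data.frame(sample_id = colnames(x), intrinsic = intrinsic,
             centroid_cor = best_cor, stringsAsFactors = FALSE)
}

#' Rescue unclassified samples as claudin-low
#'
#' Samples are split into two average-linkage groups on the
#' claudin/E-cadherin panel; candidate samples (those left unclassified
#' by the intrinsic assignment) that fall in the group with the lower
#' mean panel expression are relabelled `ClaudinLow`.
#'
#' @param ds An [expression_dataset()].
#' @param calls data.frame from [assign_intrinsic_subtypes()].
#' @param claudin Character vector of claudin/E-cadherin genes.
#' @param candidates Sample ids eligible for rescue; defaults to the
#'   samples currently `Unclassified`.
#' @return The updated calls data.frame.
#' @export
assign_claudin_low <- function(ds, calls, claudin = claudin_panel(),
                               candidates = calls$sample_id[
                                 calls$intrinsic == "Unclassified"]) {
  if (length(candidates) == 0) return(calls)
  present <- intersect(claudin, feature_ids(ds))
  if (length(present) == 0) tb_stop("no claudin panel genes present")
  if (!all(candidates %in% sample_ids(ds)))
    tb_stop("candidates must be samples of the dataset")
  x <- ds$values[present, , drop = FALSE]
  groups <- stats::cutree(stats::hclust(stats::dist(t(x)), method = "average"),
                          k = 2)
  means <- tapply(colMeans(x), groups, mean)
  low <- as.integer(names(means)[which.min(means)])
  rescued <- candidates[groups[candidates] == low]
  calls$intrinsic[calls$sample_id %in% rescued] <- "ClaudinLow"
  calls
}

#' Carey IHC surrogate subtype
#'
#' Luminal HER2- (ER+ and/or PR+, HER2-); Luminal HER2+ (ER+ and/or PR+,
#' HER2+); HER2+/ER- (ER-, PR-, HER2+); triple negative (ER-, PR-,
#' HER2-). The rules are total and mutually exclusive over the eight
#' status combinations; a missing status yields a missing class.
#'
#' @param er,pr,her2 Logical vectors (TRUE = positive), recycled to a
#'   common length.
#' @return Character vector with levels `LumHER2neg`, `LumHER2pos`,
#'   `HER2posERneg`, `TripleNeg` (NA where any status is missing).
#' @export
ihc_subtype <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(as.logical(er), n)
  pr <- rep_len(as.logical(pr), n)
  her2 <- rep_len(as.logical(her2), n)
  out <- rep(NA_character_, n)
  lum <- er | pr
  out[lum & !her2] <- "LumHER2neg"
  out[lum & her2] <- "LumHER2pos"
  out[!er & !pr & her2] <- "HER2posERneg"
  out[!er & !pr & !her2] <- "TripleNeg"
  out[is.na(er) | is.na(pr) | is.na(her2)] <- NA_character_
  out
}

#' Subtype frequency table with rounded percentages and luminal ratio
#'
#' Counts per cohort and subtype, integer percentages of the cohort total
#' (rounded half up), and the luminal A / luminal B ratio computed from
#' the rounded percentages to two decimals (undefined when the rounded
#' luminal B percentage is zero).
#'
#' @param calls Character vector of subtype labels per sample
#'   (`Unclassified` is tabulated as `Undetermined`).
#' @param cohorts Character vector of cohort labels, same length.
#' @return List with `counts`, `percentages` (matrices subtype x cohort)
#'   and `luminal_ratio` (named per cohort).
#' @export
frequency_table <- function(calls, cohorts) {
  if (length(calls) != length(cohorts)) tb_stop("calls and cohorts must match")
  calls <- ifelse(calls %in% c("Unclassified"), "Undetermined", calls)
  lev <- c("Basal", "ERBB2", "LumA", "LumB", "ClaudinLow", "Undetermined")
  lev <- lev[lev %in% calls]
  counts <- table(factor(calls, levels = lev), cohorts)
  totals <- colSums(counts)
  pct <- sweep(100 * counts, 2, totals, "/")
  pct <- apply(pct, 2, round_half_up)
  dimnames(pct) <- dimnames(counts)
  ratio <- vapply(colnames(counts), function(co) {
    if (!all(c("LumA", "LumB") %in% rownames(pct))) return(NA_real_)
    b <- pct["LumB", co]
    if (b == 0) return(NA_real_)
    round_half_up(pct["LumA", co] / b, 2)
  }, 0)
  list(counts = unclass(counts), percentages = pct, luminal_ratio = ratio)
}

#' PCA embedding and silhouette separation of two labelings
#'
#' Projects samples onto the first two principal components of the
#' feature-centered expression matrix and reports the mean silhouette
#' width of each labeling on the 2-D embedding; used to ask whether
#' samples group by molecular subtype or by cohort.
#'
#' @param ds An [expression_dataset()].
#' @param labels_a,labels_b Two labelings of the samples (each label must
#'   cover at least 3 samples).
#' @return List with `embedding` (samples x 2), `silhouette_a`,
#'   `silhouette_b`.
#' @export
pca_group_separation <- function(ds, labels_a, labels_b) {
  check_labels <- function(l, nm) {
    if (length(l) != ncol(ds$values)) tb_stop("%s must label every sample", nm)
    if (any(table(l) < 3)) tb_stop("%s: every label needs >= 3 samples", nm)
  }
  check_labels(labels_a, "labels_a"); check_labels(labels_b, "labels_b")
  pc <- stats::prcomp(t(ds$values), center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2 || pc$sdev[2] < 1e-12)
    tb_stop("degenerate data: fewer than 2 non-trivial principal components")
  emb <- pc$x[, 1:2, drop = FALSE]
  msil <- function(l) {
    f <- as.integer(factor(l))
    if (length(unique(f)) < 2) return(NA_real_)
    mean(cluster::silhouette(f, stats::dist(emb))[, "sil_width"])
  }
  list(embedding = emb, silhouette_a = msil(labels_a),
       silhouette_b = msil(labels_b))
}
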