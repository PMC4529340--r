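# Per-feature linear modelling with ethnicity and molecular subtype as
# covariates (ordinary least squares per gene; t statistics per
# contrast), BH-FDR plus fold-change significance calls, and the
# storage-time association screen.

#' Fit per-feature linear models with ethnicity and subtype covariates
#'
#' Ordinary least squares per feature on the design
#' `~ ethnicity + subtype`, with t statistics and two-sided p-values for
#' the ethnicity contrast and all pairwise subtype contrasts. Effects are
#' differences of group means on the log2 scale, so an estimate of 1
#' corresponds to a fold change of 2.
#'
#' @param ds An [expression_dataset()].
#' @param ethnicity Two-level factor (or character) per sample.
#' @param subtype Optional subtype labels per sample.
#' @param include_unclassified Keep samples labelled
#'   `Unclassified`/`Undetermined` in the subtype covariate (default:
#'   dropped from the fit).
#' @return A `DEFit`: list with `contrasts` (named list of data.frames
#'   `feature`, `log2fc`, `t`, `p`), `df_residual`, `n_used`.
#' @export
fit_linear_models <- function(ds, ethnicity, subtype = NULL,
                              include_unclassified = FALSE) {
  v <- ds$values
  if (length(ethnicity) != ncol(v)) tb_stop("ethnicity must label every sample")
  keep <- rep(TRUE, ncol(v))
  if (!is.null(subtype)) {
    if (length(subtype) != ncol(v)) tb_stop("subtype must label every sample")
    if (!include_unclassified)
      keep <- !(subtype %in% c("Unclassified", "Undetermined")) & !is.na(subtype)
  }
  v <- v[, keep, drop = FALSE]
  eth <- factor(ethnicity[keep])
  if (nlevels(eth) != 2) tb_stop("ethnicity must have exactly 2 levels")
  dat <- data.frame(ethnicity = eth)
  if (!is.null(subtype)) dat$subtype <- factor(subtype[keep])
  X <- stats::model.matrix(~ ., dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    tb_stop("rank-deficient design; aliased terms: %s",
            paste(aliased, collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  if (df < 2) tb_stop("need at least 2 residual degrees of freedom (have %d)", df)
  coef <- t(qr.coef(qrX, t(v)))           # features x p
  fitted <- coef %*% t(X)
  sigma2 <- rowSums((v - fitted)^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]

  contrasts <- list()
  # ethnicity contrast: second level minus first
  ce <- stats::setNames(numeric(ncol(X)), colnames(X))
  ce[paste0("ethnicity", levels(eth)[2])] <- 1
  contrasts[[paste0(levels(eth)[2], "_vs_", levels(eth)[1])]] <- ce
  if (!is.null(subtype)) {
    lev <- levels(dat$subtype)
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      if (j <= i) next
      cc <- stats::setNames(numeric(ncol(X)), colnames(X))
      if (i > 1) cc[paste0("subtype", lev[i])] <- -1
      cc[paste0("subtype", lev[j])] <- 1
      contrasts[[paste0(lev[j], "_vs_", lev[i])]] <- cc
    }
  }
  res <- lapply(contrasts, function(cc) {
    est <- drop(coef %*% cc)
    se <- sqrt(sigma2 * drop(t(cc) %*% xtx_inv %*% cc))
    tt <- est / se
    data.frame(feature = rownames(v), log2fc = est, t = tt,
               p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  structure(list(contrasts = res, df_residual = df, n_used = nrow(X)),
            class = "DEFit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity; order-preserving. Input
#' p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    tb_stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed features
#'
#' A feature is significant in a contrast when `fdr < fdr_cut` and
#' `|log2fc| >= log2(fc_cut)` (so the default calls features at FDR <
#' 0.05 with absolute fold change >= 2). Subtype calls use the union over
#' all pairwise subtype contrasts.
#'
#' @param fit A `DEFit` from [fit_linear_models()].
#' @param fdr_cut FDR threshold (strict `<`).
#' @param fc_cut Fold-change threshold on the natural scale (`>=`).
#' @return List with `results` (per-contrast data.frames including `fdr`
#'   and `significant`), `counts` (named per contrast), `ethnicity_de`
#'   and `subtype_de` (feature sets; the subtype set is the union over
#'   subtype contrasts).
#' @export
call_de <- function(fit, fdr_cut = 0.05, fc_cut = 2) {
  lfc_cut <- log2(fc_cut)
  results <- lapply(fit$contrasts, function(tab) {
    tab$fdr <- bh_fdr(tab$p)
    tab$significant <- tab$fdr < fdr_cut & abs(tab$log2fc) >= lfc_cut
    tab
  })
  counts <- vapply(results, function(tab) sum(tab$significant), 0L)
  eth_name <- names(results)[1]
  sub_names <- setdiff(names(results), eth_name)
  subtype_de <- unique(unlist(lapply(results[sub_names], function(tab)
    tab$feature[tab$significant])))
  list(results = results, counts = counts,
       ethnicity_de = results[[eth_name]]$feature[results[[eth_name]]$significant],
       subtype_de = if (is.null(subtype_de)) character(0) else subtype_de)
}

#' Screen features for association with pre-freezing storage time
#'
#' Per-feature simple linear regression of expression on storage hours;
#' features with nominal p < `p_cut` are flagged. The headline readout is
#' the flagged count and its overlap with breast cancer signatures.
#'
#' @param ds An [expression_dataset()].
#' @param storage_hours Numeric vector of hours per sample (non-constant).
#' @param p_cut Nominal significance threshold for flagging.
#' @return data.frame with `feature`, `slope` (log2 units per hour), `p`,
#'   `flagged`.
#' @export
storage_screen <- function(ds, storage_hours, p_cut = 0.001) {
  h <- as.numeric(storage_hours)
  v <- ds$values
  if (length(h) != ncol(v)) tb_stop("storage_hours must cover every sample")
  if (anyNA(h)) tb_stop("storage hours must be known for all samples")
  if (stats::sd(h) == 0) tb_stop("storage hours are constant; no regression possible")
  hc <- h - mean(h)
  sxx <- sum(hc^2)
  slope <- drop(v %*% hc) / sxx
  fitted <- rowMeans(v) + outer(slope, hc)
  df <- length(h) - 2
  s2 <- rowSums((v - fitted)^2) / df
  tt <- slope / sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(feature = rownames(v), slope = slope, p = p,
             flagged = p < p_cut, stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of storage-flagged features with gene signatures
#'
#' @param screen data.frame from [storage_screen()].
#' @param signatures Named list of gene sets (see [read_gmt()]).
#' @return data.frame with `signature`, `size`, `n_overlap`.
#' @export
overlap_with_signatures <- function(screen, signatures) {
  flagged <- screen$feature[screen$flagged]
  if (length(signatures) == 0)
    return(data.frame(signature = character(0), size = integer(0),
                      n_overlap = integer(0)))
  data.frame(
    signature = names(signatures),
    size = vapply(signatures, function(s)
      length(if (is.list(s)) s$members else s), 0L),
    n_overlap = vapply(signatures, function(s)
      length(intersect(flagged, if (is.list(s)) s$members else s)), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
}
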