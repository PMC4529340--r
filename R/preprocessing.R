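# Matrix-level preprocessing: log2 transform, quantile normalization,
# detection filtering, probe -> gene collapse, IQR variability filtering.
# The fixed pipeline order is log2 -> normalize -> detection filter ->
# collapse (see preprocess_dataset).

#' Keep features detected in at least `min_samples` samples
#'
#' A feature is retained when its detection p-value is below `alpha` in at
#' least `min_samples` samples; feature order is preserved.
#'
#' @param ds An [expression_dataset()] with detection p-values.
#' @param alpha Detection significance level.
#' @param min_samples Minimum number of samples with p < alpha.
#' @return The filtered dataset.
#' @export
filter_by_detection <- function(ds, alpha = 0.01, min_samples = 1L) {
  if (is.null(ds$detection_p))
    tb_stop("filter_by_detection requires detection p-values")
  keep <- rowSums(ds$detection_p < alpha) >= min_samples
  tb_log("detection filter: %d of %d features kept (p < %g in >= %d samples)",
         sum(keep), length(keep), alpha, min_samples)
  subset_dataset(ds, which(keep))
}

#' Per-probe detection rate and interquartile range
#'
#' @param ds An [expression_dataset()]; detection rates require the
#'   detection p-value matrix.
#' @param alpha Detection significance level.
#' @return data.frame with `probe_id`, `detection_rate` (fraction of
#'   samples with detection p < alpha) and `iqr` (type-7 quartiles).
#' @export
probe_stats <- function(ds, alpha = 0.01) {
  if (is.null(ds$detection_p))
    tb_stop("probe_stats requires detection p-values")
  data.frame(
    probe_id = feature_ids(ds),
    detection_rate = rowMeans(ds$detection_p < alpha),
    iqr = apply(ds$values, 1, stats::IQR, type = 7),
    stringsAsFactors = FALSE)
}

#' Collapse multiple probes per gene to one row
#'
#' For each gene symbol the probe with the highest detection rate is
#' selected; equal detection rates are broken by the larger IQR, and any
#' remaining tie by the lexicographically smallest probe id. The retained
#' row keeps its measured values; the output is indexed by gene symbol.
#'
#' @param ds An [expression_dataset()] with detection p-values.
#' @param annotation Named character vector probe id -> gene symbol (see
#'   [read_probe_annotation()]); every probe must be annotated.
#' @param alpha Detection significance level used for the rates.
#' @return Dataset with one row per gene symbol.
#' @export
collapse_probes <- function(ds, annotation, alpha = 0.01) {
  probes <- feature_ids(ds)
  missing <- setdiff(probes, names(annotation))
  if (length(missing))
    tb_stop("unannotated probes: %s%s",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  st <- probe_stats(ds, alpha = alpha)
  st$symbol <- unname(annotation[st$probe_id])
  # order: by symbol, then detection rate desc, IQR desc, probe id asc;
  # the first probe within each symbol wins
  ord <- order(st$symbol, -st$detection_rate, -st$iqr, st$probe_id)
  st <- st[ord, ]
  winners <- st[!duplicated(st$symbol), ]
  out <- subset_dataset(ds, match(winners$probe_id, probes))
  rownames(out$values) <- winners$symbol
  if (!is.null(out$detection_p)) rownames(out$detection_p) <- winners$symbol
  tb_log("collapsed %d probes to %d gene symbols", length(probes), nrow(winners))
  out
}

#' Quantile normalization
#'
#' Forces every sample to share the same distribution: after
#' normalization the sorted values of each column equal the mean of the
#' per-rank values across columns, while within-column ranks are
#' preserved. This is the distribution-alignment stage of the pipeline
#' (logged as such).
#'
#' @param ds An [expression_dataset()] with at least 2 samples.
#' @return The normalized dataset.
#' @export
quantile_normalize <- function(ds) {
  if (ncol(ds$values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged",
            call. = FALSE)
    return(ds)
  }
  v <- limma::normalizeQuantiles(ds$values)
  dimnames(v) <- dimnames(ds$values)
  tb_log("quantile normalization applied to %d samples", ncol(v))
  expression_dataset(v, detection_p = ds$detection_p, cohort = ds$cohort)
}

#' Keep features whose IQR exceeds a threshold
#'
#' Quartiles use linear interpolation between order statistics (the
#' common type-7 rule); the comparison is strict (`IQR > min_iqr`), so a
#' constant feature is always removed for any non-negative threshold.
#'
#' @param ds An [expression_dataset()].
#' @param min_iqr Strict lower bound on the interquartile range.
#' @return The filtered dataset.
#' @export
iqr_filter <- function(ds, min_iqr) {
  if (!is.numeric(min_iqr) || min_iqr < 0)
    tb_stop("min_iqr must be a non-negative number")
  iqrs <- apply(ds$values, 1, stats::IQR, type = 7)
  keep <- iqrs > min_iqr
  tb_log("IQR filter: %d of %d features with IQR > %g", sum(keep),
         length(keep), min_iqr)
  subset_dataset(ds, which(keep))
}

#' Log2-transform when the data look like raw intensities
#'
#' Data with a maximum value at or below 30 are assumed to be on the log2
#' scale already; otherwise `log2(x + 1)` is applied with a warning.
#'
#' @param ds An [expression_dataset()].
#' @return Dataset on the log2 scale.
#' @export
ensure_log2 <- function(ds) {
  if (max(ds$values) <= 30) return(ds)
  warning("values exceed 30; applying log2(x + 1)", call. = FALSE)
  expression_dataset(log2(ds$values + 1), detection_p = ds$detection_p,
                     cohort = ds$cohort)
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: log2 transform (if needed), quantile normalization,
#' detection filtering, and, when a probe annotation is supplied, probe
#' collapse to gene symbols. Re-running on the same input is
#' deterministic.
#'
#' @param ds An [expression_dataset()] with detection p-values.
#' @param annotation Optional probe -> symbol map for collapsing.
#' @param alpha,min_samples Detection filter parameters.
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(ds, annotation = NULL, alpha = 0.01,
                               min_samples = 1L) {
  ds <- ensure_log2(ds)
  ds <- quantile_normalize(ds)
  ds <- filter_by_detection(ds, alpha = alpha, min_samples = min_samples)
  if (!is.null(annotation)) ds <- collapse_probes(ds, annotation, alpha = alpha)
  ds
}
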