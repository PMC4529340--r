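#' Construct an expression dataset
#'
#' The container consumed by every pipeline stage: a feature x sample matrix
#' of log2 intensities, an optional matrix of per-feature per-sample
#' detection p-values of the same shape, and a cohort label.
#'
#' @param values Numeric matrix (features x samples) with unique, non-empty
#'   rownames (feature ids) and colnames (sample ids). All values must be
#'   finite.
#' @param detection_p Optional numeric matrix of the same dimensions with
#'   values in \[0, 1\]; per-sample probability that the observed intensity
#'   arises from background.
#' @param cohort Single string labelling the cohort (e.g. `"chinese"`).
#' @return An object of class `ExpressionDataset` (a list with elements
#'   `values`, `detection_p`, `cohort`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ds <- expression_dataset(m, cohort = "demo")
#' dim(ds)
#' @export
expression_dataset <- function(values, detection_p = NULL,
                               cohort = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    tb_stop("'values' must be a numeric matrix")
  if (nrow(values) == 0 || ncol(values) == 0)
    tb_stop("empty expression matrix (%d features x %d samples)",
            nrow(values), ncol(values))
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    tb_stop("feature ids (rownames) must be present and non-empty")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    tb_stop("sample ids (colnames) must be present and non-empty")
  if (anyDuplicated(fid))
    tb_stop("duplicate feature ids: %s",
            paste(unique(fid[duplicated(fid)])[1:min(3, sum(duplicated(fid)))],
                  collapse = ", "))
  if (anyDuplicated(sid))
    tb_stop("duplicate sample ids: %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values)))
    tb_stop("expression values must be finite (no NA/NaN/Inf); %d offending cells",
            sum(!is.finite(values)))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values)))
      tb_stop("detection_p must be a matrix with the same shape as values")
    if (any(!is.finite(detection_p)) ||
        any(detection_p < 0) || any(detection_p > 1))
      tb_stop("detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p,
                 cohort = as.character(cohort)),
            class = "ExpressionDataset")
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d features x %d samples (cohort: %s)%s\n",
              nrow(x$values), ncol(x$values), x$cohort,
              if (is.null(x$detection_p)) "" else ", with detection p-values"))
  invisible(x)
}

#' Feature and sample ids of a dataset
#' @param ds An `ExpressionDataset`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(ds) rownames(ds$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(ds) colnames(ds$values)

# Subset features (and optionally samples), keeping detection_p aligned.
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  f <- if (is.null(features)) seq_len(nrow(ds$values)) else features
  s <- if (is.null(samples)) seq_len(ncol(ds$values)) else samples
  expression_dataset(ds$values[f, s, drop = FALSE],
                     detection_p = if (is.null(ds$detection_p)) NULL else
                       ds$detection_p[f, s, drop = FALSE],
                     cohort = ds$cohort)
}
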