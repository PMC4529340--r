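# Clinico-pathological statistics: contingency tests, Cohen's kappa,
# partial correlation, and the rounded percentage/ratio arithmetic used
# in the cohort tables.

as_count_table <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) tb_stop("counts must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2) tb_stop("need at least a 2x2 table")
  m
}

#' Pearson chi-square test on a contingency table
#'
#' For 2x2 tables the Yates continuity correction is applied by default:
#' that is the convention the cohort tables report (a no-correction flag
#' exists). Degrees of freedom are `(r-1)(c-1)`.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param continuity_correction Apply Yates correction (2x2 only).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(table, continuity_correction = TRUE) {
  m <- as_count_table(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    tb_stop("zero marginal total; expected counts undefined")
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity_correction))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p: the sum of probabilities, under the hypergeometric
#' null with fixed margins, of all tables no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as_count_table(table)
  if (!all(dim(m) == 2)) tb_stop("Fisher's exact test here requires a 2x2 table")
  stats::fisher.test(m)$p.value
}

#' Cohen's kappa for a square agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (the
#' diagonal fraction) and chance agreement `p_e` from the margins.
#'
#' @param table k x k matrix of counts (raters in rows/columns).
#' @return Kappa (in \[-1, 1\]).
#' @export
cohens_kappa <- function(table) {
  m <- as_count_table(table)
  if (nrow(m) != ncol(m)) tb_stop("kappa needs a square table")
  n <- sum(m)
  if (n == 0) tb_stop("empty table")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12)
    tb_stop("degenerate margins (chance agreement = 1); kappa undefined")
  (po - pe) / (1 - pe)
}

#' Partial correlation of two variables given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariates, with a t-based p-value on
#' `n - #covariates - 2` degrees of freedom. With no covariates this is
#' the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data.frame of controlling
#'   variables (columns), full rank.
#' @return List with `r_partial`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) tb_stop("x and y must have equal length")
  q <- 0
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) tb_stop("covariates must have one row per observation")
    q <- ncol(Z)
    X <- cbind(1, Z)
    if (qr(X)$rank < ncol(X)) tb_stop("collinear covariates")
    x <- stats::lsfit(Z, x)$residuals
    y <- stats::lsfit(Z, y)$residuals
  }
  if (n <= q + 2) tb_stop("need n > #covariates + 2")
  r <- stats::cor(x, y)
  df <- n - q - 2
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r_partial = r, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Rounded percentages and a ratio of two of them
#'
#' Integer percentages of `total` rounded half up, as printed in the
#' cohort tables; the optional ratio is taken between the first two
#' rounded percentages to two decimals (the convention that turns counts
#' 21 and 23 of 78 into 27% / 29% = 0.93).
#'
#' @param counts Named or unnamed vector of counts.
#' @param total Positive denominator.
#' @return List with `percentages` and, when at least two counts are
#'   given, `ratio` (`NA` when the second percentage rounds to zero).
#' @export
percentage_and_ratio <- function(counts, total) {
  if (!is.numeric(total) || total <= 0) tb_stop("total must be positive")
  pct <- round_half_up(100 * counts / total)
  out <- list(percentages = pct)
  if (length(counts) >= 2)
    out$ratio <- if (pct[2] == 0) NA_real_ else round_half_up(pct[1] / pct[2], 2)
  out
}
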