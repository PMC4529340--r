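# Shared fixture builders for the suite. Everything is generated in code;
# no data files.

# A small matrix dataset with ids.
toy_dataset <- function(values, cohort = "toy", detection_p = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_dataset(values, detection_p = detection_p, cohort = cohort)
}

# Gaussian noise dataset.
noise_dataset <- function(n_feat, n_samp, sd = 1, seed = 1, cohort = "noise") {
  withr::with_seed(seed,
    toy_dataset(matrix(rnorm(n_feat * n_samp, 8, sd), n_feat, n_samp),
                cohort = cohort))
}

# A compact simulation configuration for unit tests (fast but structured).
small_config <- function(...) {
  simulation_config(
    n_samples_per_cohort = 60, n_genes = 400, n_mirnas = 120,
    modules = list(list(size = 15, latent_loading = 0.9, shared = TRUE),
                   list(size = 12, latent_loading = 0.9, shared = TRUE),
                   list(size = 10, latent_loading = 0.9, shared = FALSE)),
    mirna_modules = list(list(size = 8, latent_loading = 0.9, shared = TRUE)),
    ...)
}

# Independent brute-force IQR (type-7 quartiles) used as oracle.
oracle_iqr <- function(x) {
  q <- function(p) {
    xs <- sort(x); n <- length(xs)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  q(0.75) - q(0.25)
}

# Exhaustive hypergeometric upper tail (enumeration oracle).
oracle_hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Independent weighted-KS enrichment score (plain running-sum loop).
oracle_es <- function(scores_desc, is_hit) {
  nr <- sum(abs(scores_desc[is_hit]))
  w <- if (nr == 0) rep(1 / sum(is_hit), length(scores_desc))
       else abs(scores_desc) / nr
  run <- 0; best <- -Inf
  miss_step <- 1 / sum(!is_hit)
  for (i in seq_along(scores_desc)) {
    run <- run + if (is_hit[i]) w[i] else -miss_step
    best <- max(best, run)
  }
  best
}

jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Merge two cohorts of a generated pair into one dataset with labels.
merge_pair <- function(pair) {
  v <- cbind(pair$cohort_a$values, pair$cohort_b$values)
  list(ds = expression_dataset(v, cohort = "merged"),
       ethnicity = rep(c("chinese", "caucasian"),
                       c(ncol(pair$cohort_a$values), ncol(pair$cohort_b$values))),
       subtype = unname(pair$truth$subtype_labels[colnames(v)]))
}
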