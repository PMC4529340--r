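# Per-feature OLS contrasts, BH-FDR, significance calls, storage screen.

test_that("two-group fit equals the pooled-variance t-test", {
  withr::local_seed(501)
  y <- matrix(rnorm(60 * 24, 8), 60, 24,
              dimnames = list(sprintf("g%03d", 1:60), sprintf("s%02d", 1:24)))
  g <- rep(c("ch", "it"), each = 12)
  fit <- fit_linear_models(expression_dataset(y), g)
  ref_t <- vapply(seq_len(60), function(i)
    unname(t.test(y[i, g == "it"], y[i, g == "ch"], var.equal = TRUE)$statistic),
    0)
  tab <- fit$contrasts$it_vs_ch
  expect_lt(max(abs(tab$t - ref_t)), 1e-10)
  expect_equal(tab$log2fc,
               rowMeans(y[, g == "it"]) - rowMeans(y[, g == "ch"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-noise equal group means give zero contrast estimates", {
  y <- matrix(5, 20, 12, dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  y <- y + seq_len(20) * 0.1                # per-feature offsets only
  g <- rep(c("a", "b"), 6)
  st <- rep(c("LumA", "LumB", "Basal"), each = 4)
  withr::local_seed(505)
  fit <- fit_linear_models(expression_dataset(
    y + matrix(rnorm(240, 0, 1e-8), 20, 12)), g, st)
  for (tab in fit$contrasts)
    expect_lt(max(abs(tab$log2fc)), 1e-6)
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  y <- matrix(rnorm(40, 8), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  eth <- rep(c("a", "b"), each = 5)
  st <- ifelse(eth == "a", "LumA", "LumB")   # confounded with ethnicity
  expect_error(fit_linear_models(expression_dataset(y), eth, st),
               "rank-deficient")
})

test_that("null fits give uniform p-values at nominal type-I rate", {
  withr::local_seed(511)
  y <- matrix(rnorm(1000 * 40, 8), 1000, 40,
              dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:40)))
  g <- rep(c("ch", "it"), each = 20)
  fit <- fit_linear_models(expression_dataset(y), g)
  p <- fit$contrasts[[1]]$p
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # brute-force step-up implementation on many random vectors
  brute_bh <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  withr::local_seed(521)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  # adjusted >= raw; non-decreasing in sorted order
  p <- runif(50)
  a <- bh_fdr(p)
  expect_true(all(a >= p - 1e-15))
  expect_true(all(diff(a[order(p)]) > -1e-15))
})

test_that("significance calls honour the joint FDR and fold-change rule", {
  fit <- structure(list(contrasts = list(
    eth = data.frame(feature = paste0("g", 1:4),
                     log2fc = c(1.0, 0.99, 3, 0.2),
                     t = rep(5, 4),
                     p = c(0.049, 0.001, 0.002, 0.6))),
    df_residual = 10, n_used = 12), class = "DEFit")
  # single contrast: fdr = BH of the 4 p-values
  de <- call_de(fit)
  tab <- de$results$eth
  expect_true(tab$significant[3])                 # fdr small, fc large
  expect_false(tab$significant[2])                # |log2fc| < 1
  expect_false(tab$significant[4])
  # boundary: log2fc exactly 1 called iff fdr < 0.05
  expect_equal(tab$significant[1], tab$fdr[1] < 0.05 & abs(tab$log2fc[1]) >= 1)
})

test_that("subtype contrasts outnumber ethnicity calls on batch-free data", {
  cfg <- small_config(seed = 531)
  pair <- suppressMessages(generate_cohort_pair(cfg))
  m <- merge_pair(pair)
  fit <- fit_linear_models(m$ds, m$ethnicity, m$subtype)
  de <- call_de(fit)
  eth <- de$counts[grep("chinese|caucasian", names(de$counts))]
  subs <- de$counts[setdiff(names(de$counts), names(eth))]
  expect_gt(sum(subs), eth)
  expect_lte(eth, 2)       # essentially no ethnicity signal without a batch
  # an additive cohort shift of 1 log2 unit flips the comparison
  cfg2 <- small_config(seed = 531, batch_shift = 1)
  pair2 <- suppressMessages(generate_cohort_pair(cfg2))
  m2 <- merge_pair(pair2)
  de2 <- call_de(fit_linear_models(m2$ds, m2$ethnicity, m2$subtype))
  eth2 <- de2$counts[grep("chinese|caucasian", names(de2$counts))]
  expect_gt(eth2, 50)
})

test_that("storage screen flags planted hour-dependent genes", {
  cfg <- simulation_config(n_samples_per_cohort = 90, n_genes = 1000,
                           n_mirnas = 50, modules = list(),
                           mirna_modules = list(),
                           storage_effect = list(n_genes_affected = 10,
                                                 slope = 0.3),
                           seed = 541)
  pair <- generate_cohort_pair(cfg)
  hours <- pair$truth$annotation$storage_hours[
    pair$truth$annotation$cohort == "caucasian"]
  scr <- storage_screen(pair$cohort_b, hours)
  planted <- pair$truth$storage_genes
  expect_gte(sum(scr$flagged & scr$feature %in% planted), 8)
  false_flags <- sum(scr$flagged & !scr$feature %in% planted)
  expect_lte(false_flags, 10)     # ~ 1000 x 0.001 expected under the null
  expect_error(storage_screen(pair$cohort_b, rep(2, 90)), "constant")
  # signature overlap bookkeeping
  ov <- overlap_with_signatures(scr, list(S1 = list(name = "S1",
    description = "", members = planted[1:3]), S2 = list(name = "S2",
    description = "", members = "not_a_gene")))
  expect_equal(ov$n_overlap[ov$signature == "S2"], 0)
  expect_gte(ov$n_overlap[ov$signature == "S1"], 2)
  expect_equal(nrow(overlap_with_signatures(scr, list())), 0)
})

test_that("null storage screen false-flag count is binomial-small", {
  ds <- noise_dataset(1000, 60, seed = 551)
  hours <- withr::with_seed(552, runif(60, 1, 4))
  scr <- storage_screen(ds, hours)
  expect_lte(sum(scr$flagged), 8)   # Binomial(1000, 0.001), far tail at 8
})
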