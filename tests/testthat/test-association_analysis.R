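test_that("two-group comparison reports median difference and exact p", {
  auc <- c(S1 = 3, S2 = 4, S3 = 5, S4 = 1, S5 = 2)
  res <- compare_groups(auc, c("S1", "S2", "S3"), c("S4", "S5"))
  expect_equal(res$effect, 4 - 1.5)
  expect_equal(res$direction, "positive")
  # exact enumeration over all 10 rank splits
  expect_equal(res$p_unadjusted, oracle_mw_exact(c(3, 4, 5), c(1, 2)))
  expect_equal(res$p_unadjusted, 0.2)

  # identical multisets: zero effect, p = 1
  auc2 <- c(A1 = 1, A2 = 2, A3 = 3, B1 = 1, B2 = 2, B3 = 3)
  null <- compare_groups(auc2, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expect_equal(null$effect, 0)
  expect_equal(null$direction, "zero")
  expect_equal(null$p_unadjusted, 1)

  expect_error(compare_groups(auc, "S1", c("S4", "S5")), "too small")
})

test_that("exact Mann-Whitney p agrees with full enumeration on small
          tie-free groups", {
  set.seed(12)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 4)
    b <- round(rnorm(sample(3:6, 1)) + runif(1, -1, 1), 4)
    auc <- c(a, b)
    names(auc) <- paste0("S", seq_along(auc))
    res <- compare_groups(auc, names(auc)[seq_along(a)],
                          names(auc)[-seq_along(a)])
    expect_equal(res$p_unadjusted, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
})

test_that("a strong shift is detected as a positive trend", {
  set.seed(77)
  hits <- 0
  for (i in 1:100) {
    b <- rnorm(50)
    a <- rnorm(50) + 10
    auc <- c(a, b)
    names(auc) <- paste0("S", 1:100)
    res <- compare_groups(auc, paste0("S", 1:50), paste0("S", 51:100))
    if (res$direction == "positive" && res$p_unadjusted < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 99)
})

test_that("Spearman correlation follows the rank definition", {
  scores <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4, S5 = 5)
  auc <- c(S1 = 10, S2 = 20, S3 = 30, S4 = 40, S5 = 50)
  res <- correlate_score(auc, scores)
  expect_equal(res$effect, 1)
  expect_equal(res$direction, "positive")

  # closed form 1 - 6*sum(d^2)/(n(n^2-1)) on a hand-ranked tie-free example
  auc2 <- c(S1 = 12, S2 = 31, S3 = 25, S4 = 47, S5 = 40)
  r2 <- correlate_score(auc2, scores)
  d <- rank(scores) - rank(auc2)
  expect_equal(r2$effect, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)

  expect_error(correlate_score(auc[1:2], scores), "need >= 3")
  expect_error(correlate_score(auc * 0, scores), "constant")
})

test_that("null correlations are calibrated near the nominal level", {
  set.seed(31)
  n_rep <- 400
  p <- numeric(n_rep)
  scores <- stats::setNames(rnorm(60), paste0("S", 1:60))
  for (i in seq_len(n_rep)) {
    auc <- stats::setNames(rnorm(60), paste0("S", 1:60))
    p[i] <- correlate_score(auc, scores)$p_unadjusted
  }
  frac <- mean(p < 0.05)
  # 99% binomial band around 0.05 at 400 draws
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("Holm adjustment matches its step-down definition", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("assay filtering drops assays with too few altered samples", {
  set.seed(2)
  ids <- paste0("S", 1:30)
  auc <- matrix(rnorm(30 * 3), 30, 3,
                dimnames = list(ids, c("a1", "a2", "a3")))
  auc[ids[1], "a2"] <- NA       # only 9 of the 10 altered samples measured
  meta <- data.frame(assay_id = c("a1", "a2", "a3"),
                     drug_name = "d", compound_id = "c", source = "s",
                     category = "Platinum")
  assays <- drug_assay_set(meta, auc)
  altered <- ids[1:10]
  kept <- filter_assays(assays, altered, min_altered = 10)
  expect_false("a2" %in% colnames(kept$auc))
  expect_true(all(c("a1", "a3") %in% colnames(kept$auc)))
  expect_equal(attr(kept, "exclusions")$assay_id, "a2")
  # boundary: exactly min_altered measured altered samples is kept
  kept2 <- filter_assays(assays, altered, min_altered = 9)
  expect_true("a2" %in% colnames(kept2$auc))
  # empty assay list stays empty
  empty <- filter_assays(drug_assay_set(meta[0, ], auc[, 0, drop = FALSE]),
                         altered)
  expect_equal(ncol(empty$auc), 0)
})

test_that("family-level association is order-invariant and audits skips", {
  set.seed(14)
  cfg <- cohort_config(n_samples = 80, seed = 8)
  co <- simulate_cohort(cfg)
  scores <- stats::setNames(co$ledger$hrd_score, co$ledger$sample_id)
  res <- associate_assays(co$assays, "score", scores = scores)
  expect_true(all(res$p_adjusted >= res$p_unadjusted))
  expect_equal(res$trend, res$p_unadjusted < 0.05)
  expect_equal(res$significant, res$p_adjusted < 0.05)
  expect_true(all(res$direction[res$effect > 0] == "positive"))

  # permuting assay columns changes no per-assay number
  perm <- sample(ncol(co$assays$auc))
  assays_perm <- drug_assay_set(co$assays$meta[perm, ],
                                co$assays$auc[, perm])
  res_perm <- associate_assays(assays_perm, "score", scores = scores)
  res_perm <- res_perm[match(res$assay_id, res_perm$assay_id), ]
  expect_equal(res_perm$p_unadjusted, res$p_unadjusted)
  expect_equal(res_perm$p_adjusted, res$p_adjusted)

  # an untestable assay is skipped with a reason, not an error
  auc <- co$assays$auc
  auc[, 1] <- auc[1, 1]          # constant vector
  res2 <- associate_assays(drug_assay_set(co$assays$meta, auc),
                           "score", scores = scores)
  excl <- attr(res2, "exclusions")
  expect_equal(excl$assay_id, colnames(auc)[1])
  expect_match(excl$reason, "constant")
})

test_that("panel summaries split by direction and order by p", {
  res <- data.frame(
    assay_id = c("a", "b", "c", "d"),
    category = c("Platinum", "Platinum", "PARP inhibitor", "Others"),
    effect = c(0.5, -0.2, 0.8, 0.1),
    p_unadjusted = c(0.001, 0.2, 0.04, 0.5),
    p_adjusted = c(0.004, 0.6, 0.12, 1),
    direction = c("positive", "negative", "positive", "positive"),
    trend = c(TRUE, FALSE, TRUE, FALSE),
    significant = c(TRUE, FALSE, FALSE, FALSE))
  rep <- summarize_panel(res)
  expect_equal(rep$positive$assay_id, c("a", "c", "d"))
  expect_equal(rep$negative$assay_id, "b")
  cc <- rep$class_counts
  expect_equal(cc$n_trend[cc$category == "Platinum"], 1)
  expect_equal(cc$n_significant[cc$category == "Platinum"], 1)

  empty <- summarize_panel(res[0, ])
  expect_equal(nrow(empty$positive), 0)

  plat <- summarize_panel(res, drug_class_filter = "Platinum")
  expect_equal(nrow(plat$positive) + nrow(plat$negative), 2)
})
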