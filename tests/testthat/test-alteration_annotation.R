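test_that("the shipped configuration carries the analysis constants", {
  cfg <- default_config()
  expect_length(hr_gene_panel(cfg), 29)
  expect_true(all(c("BRCA1", "BRCA2", "RAD51C", "CDK12", "RPA1") %in%
                    hr_gene_panel(cfg)))
  expect_length(predictor_names(cfg), 10)
  expect_length(drug_categories(cfg), 24)
  expect_true("Others" %in% drug_categories(cfg))
})

test_that("the dataset-annotation filter keeps exactly the damaging label", {
  m <- rbind(mut_row("S1", "BRCA1", dataset_annotation = "damaging"),
             mut_row("S2", "BRCA1", dataset_annotation = "silent"),
             mut_row("S3", "BRCA1", dataset_annotation = "Damaging"))
  kept <- filter_deleterious_ccle(m)
  expect_equal(kept$sample_id, "S1")        # case-sensitive by default
  expect_equal(nrow(filter_deleterious_ccle(m[0, ])), 0)
})

test_that("the predictor-consensus filter implements the all-of-10 rule", {
  trunc <- mut_row("S1", "BRCA2", variant_class = "truncating",
                   predictor_call = NA)
  expect_equal(nrow(filter_deleterious_clp(trunc)), 1)

  mis_all <- mut_row("S2", "ATM", variant_class = "missense",
                     predictor_call = "damaging")
  expect_equal(nrow(filter_deleterious_clp(mis_all)), 1)

  mis_nine <- mut_row("S3", "ATM", variant_class = "missense",
                      predictor_call = "deleterious")
  mis_nine[["M-CAP"]] <- "tolerated"
  expect_equal(nrow(filter_deleterious_clp(mis_nine)), 0)

  mis_missing <- mut_row("S4", "ATM", variant_class = "missense",
                         predictor_call = "deleterious")
  mis_missing[["SIFT"]] <- NA
  expect_warning(out <- filter_deleterious_clp(mis_missing), "missing")
  expect_equal(nrow(out), 0)

  other <- mut_row("S5", "ATM", variant_class = "other",
                   predictor_call = "damaging")
  expect_equal(nrow(filter_deleterious_clp(other)), 0)
})

test_that("locus-specific LOH follows the minor-allele rule with fallback", {
  expect_equal(annotate_loh(0), "LOH_present")
  expect_equal(annotate_loh(2), "LOH_absent")
  expect_equal(annotate_loh(NA), "unknown")
  expect_equal(annotate_loh(NA, 0), "LOH_present")
  expect_equal(annotate_loh(NA, 1), "LOH_absent")
  expect_equal(annotate_loh(NA, NA), "unknown")
  expect_equal(annotate_loh(c(0, 1, NA), c(5, 5, NA)),
               c("LOH_present", "LOH_absent", "unknown"))
})

test_that("RRBS-style BRCA1 methylation needs both regions and silenced
          expression", {
  expect_true(call_brca1_methylation_ccle(c(0.8, 0.7), 2))
  expect_false(call_brca1_methylation_ccle(c(0.8, 0.1), 2))
  expect_false(call_brca1_methylation_ccle(c(0.8, 0.7), 50))
  expect_false(call_brca1_methylation_ccle(c(0.3, 0.7), 2))  # strict >
  expect_warning(res <- call_brca1_methylation_ccle(c(0.8, NA), 2), "NA")
  expect_true(is.na(res))
})

test_that("array-style BRCA1 methylation needs 15 of 17 qualifying probes", {
  expect_true(call_brca1_methylation_clp(rep(0.9, 17), 5))
  expect_false(call_brca1_methylation_clp(c(rep(0.9, 14), rep(0.05, 3)), 5))
  expect_true(call_brca1_methylation_clp(c(rep(0.9, 15), rep(0.05, 2)), 5))
  expect_false(call_brca1_methylation_clp(rep(0.9, 17), 60))
  expect_warning(res <- call_brca1_methylation_clp(rep(0.9, 13), 5),
                 "13 of 17")
  expect_true(is.na(res))
})

test_that("expression percentiles rank across the cohort on a 0-100 scale", {
  x <- c(5, 1, 3, 2, 4)
  pct <- expression_percentile(x)
  expect_equal(pct, c(100, 0, 50, 25, 75))
  expect_true(expression_percentile(c(0.5, 2:20))[1] < 10)
})

test_that("group assignment follows the alteration hierarchy", {
  ids <- paste0("S", 1:7)
  del <- rbind(
    cbind(mut_row("S1", "BRCA2"), loh = "LOH_present"),
    cbind(mut_row("S2", "ATM"), loh = "LOH_absent"),
    cbind(mut_row("S3", "PALB2"), loh = "LOH_present"),
    cbind(mut_row("S4", "CHEK2"), loh = "unknown"),
    cbind(mut_row("S6", "TP53"), loh = "LOH_present"),   # non-panel
    cbind(mut_row("S7", " brca1 "), loh = "LOH_present") # dialect drift
  )
  ann <- assign_groups(del, methylated = "S5", sample_ids = ids)
  expect_equal(ann$group,
               c("BRCA_altered",   # BRCA2 mutation with LOH
                 "HRR_LOH_neg",    # ATM without LOH
                 "HRR_LOH_pos",    # PALB2 with LOH
                 "excluded",       # unknown LOH only
                 "BRCA_altered",   # methylation without mutation
                 "WT",             # non-panel mutation never counts
                 "BRCA_altered"))  # case/whitespace-insensitive match

  grp_brca <- comparison_groups(ann, "brca_vs_wt")
  expect_setequal(grp_brca$altered, c("S1", "S5", "S7"))
  expect_setequal(grp_brca$wt, "S6")

  grp_hrr <- comparison_groups(ann, "hrr_vs_wt")
  expect_setequal(grp_hrr$altered, c("S1", "S3", "S5", "S7"))
  expect_equal(grp_brca$wt, grp_hrr$wt)
  expect_true(all(grp_brca$altered %in% grp_hrr$altered))

  grp_loose <- comparison_groups(ann, "hrr_vs_wt",
                                 require_loh_for_hrr = FALSE)
  expect_true("S2" %in% grp_loose$altered)
})

test_that("grouping is a pure function and scheme relations hold on
          simulated cohorts", {
  cfg <- cohort_config(n_samples = 60, seed = 21)
  co <- simulate_cohort(cfg)
  del <- filter_deleterious_ccle(co$mutations)
  del$loh <- annotate_loh(del$minor_cn, del$minor_cn_other)
  meth <- co$ledger$sample_id[co$ledger$methylated]
  ids <- co$ledger$sample_id
  a1 <- assign_groups(del, meth, ids)
  a2 <- assign_groups(del, meth, ids)
  expect_identical(a1, a2)
  expect_equal(a1$group, co$ledger$group)
  # BRCA-altered set nests inside the HRR-altered set; WT sets identical
  g1 <- comparison_groups(a1, "brca_vs_wt")
  g2 <- comparison_groups(a1, "hrr_vs_wt")
  expect_true(all(g1$altered %in% g2$altered))
  expect_identical(g1$wt, g2$wt)
})
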