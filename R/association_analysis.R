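#' Drug-assay container
#'
#' One drug screen is represented as assay metadata plus an AUC matrix.
#' AUC is the area under the dose-response viability curve; a higher AUC
#' means the cell line is more resistant to the drug in that assay. The
#' same drug may appear in several assays (different screens/conditions);
#' assays are always analysed separately.
#'
#' @param meta data.frame with columns `assay_id`, `drug_name`,
#'   `compound_id`, `source`, `category`; `assay_id` unique. Categories
#'   outside the configured 24-class vocabulary are remapped to `"Others"`
#'   with a warning.
#' @param auc numeric matrix, samples in rows (rownames = sample ids),
#'   assays in columns (colnames = assay ids); `NA` = not measured.
#' @param categories allowed category vocabulary.
#' @return list of class `drug_assay_set` with elements `meta` and `auc`.
#' @export
drug_assay_set <- function(meta, auc, categories = drug_categories()) {
  req <- c("assay_id", "drug_name", "compound_id", "source", "category")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    stop("assay metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$assay_id)) stop("assay_id values must be unique")
  if (!setequal(colnames(auc), meta$assay_id)) {
    stop("AUC matrix columns must match assay metadata assay_id")
  }
  if (any(is.infinite(auc))) stop("AUC values must be finite or NA")
  unknown <- !(meta$category %in% categories)
  if (any(unknown)) {
    warning(sum(unknown), " assay(s) with unknown drug category mapped to ",
            "'Others': ", paste(unique(meta$category[unknown]), collapse = ", "))
    meta$category[unknown] <- "Others"
  }
  auc <- auc[, meta$assay_id, drop = FALSE]
  structure(list(meta = meta, auc = auc), class = "drug_assay_set")
}

#' Read assay metadata and AUC matrix from CSV files
#'
#' @param meta_path CSV with the [drug_assay_set()] metadata columns.
#' @param auc_path CSV with samples in rows (first column `sample_id`) and
#'   assays in columns.
#' @inheritParams drug_assay_set
#' @return a `drug_assay_set`.
#' @export
read_assay_set <- function(meta_path, auc_path,
                           categories = drug_categories()) {
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  aucdf <- utils::read.csv(auc_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  auc <- as.matrix(aucdf[, -1, drop = FALSE])
  rownames(auc) <- aucdf[[1]]
  drug_assay_set(meta, auc, categories)
}

#' Exclude assays with too few altered samples
#'
#' Drops assays for which fewer than `min_altered` annotated-altered
#' samples have a measured (non-missing) AUC; such assays cannot support a
#' group comparison. The dropped assays are recorded in an `exclusions`
#' attribute (assay_id, reason), mirroring the audit table a screening
#' analysis should keep.
#'
#' @param assays a [drug_assay_set()].
#' @param altered character vector of altered sample ids.
#' @param min_altered minimum number of altered samples with AUC.
#' @return a filtered `drug_assay_set` with an `exclusions` attribute.
#' @export
filter_assays <- function(assays, altered, min_altered = 10) {
  stopifnot(inherits(assays, "drug_assay_set"))
  present <- intersect(altered, rownames(assays$auc))
  n_measured <- colSums(!is.na(assays$auc[present, , drop = FALSE]))
  keep <- n_measured >= min_altered
  excl <- data.frame(
    assay_id = colnames(assays$auc)[!keep],
    reason = sprintf("only %d altered samples with AUC (< %d)",
                     n_measured[!keep], min_altered),
    stringsAsFactors = FALSE
  )
  out <- drug_assay_set(assays$meta[keep[assays$meta$assay_id], , drop = FALSE],
                        assays$auc[, keep, drop = FALSE])
  attr(out, "exclusions") <- excl
  out
}

direction_of <- function(effect) {
  if (effect > 0) "positive" else if (effect < 0) "negative" else "zero"
}

#' Two-group AUC comparison for one assay
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the AUC values of
#' group A against group B, with effect summarised as
#' `median(AUC_A) - median(AUC_B)`. Samples without an AUC in this assay
#' are dropped pairwise, never imputed. The exact null distribution is
#' used for small tie-free groups, otherwise the normal approximation with
#' tie and continuity correction.
#'
#' @param auc named numeric vector of AUC values (names = sample ids).
#' @param group_a,group_b character vectors of sample ids.
#' @return one-row data.frame: `test`, `n_a`, `n_b`, `effect`,
#'   `p_unadjusted`, `direction`.
#' @export
compare_groups <- function(auc, group_a, group_b) {
  xa <- auc[intersect(group_a, names(auc))]
  xb <- auc[intersect(group_b, names(auc))]
  xa <- xa[!is.na(xa)]
  xb <- xb[!is.na(xb)]
  if (length(xa) < 2 || length(xb) < 2) {
    stop("group too small: ", length(xa), " vs ", length(xb),
         " samples with AUC (need >= 2 each)")
  }
  p <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided")$p.value
  )
  effect <- stats::median(xa) - stats::median(xb)
  data.frame(test = "mann_whitney", n_a = length(xa), n_b = length(xb),
             effect = effect, p_unadjusted = p,
             direction = direction_of(effect), stringsAsFactors = FALSE)
}

#' Score-AUC correlation for one assay
#'
#' Spearman rank correlation between a per-sample score (HRD score or
#' signature-3 similarity) and the assay's AUC over the samples having
#' both, with the two-sided p from the t-approximation on rho
#' (average-rank ties).
#'
#' @param auc named numeric vector of AUC values.
#' @param scores named numeric vector of per-sample scores.
#' @return one-row data.frame: `test`, `n`, `effect` (rho),
#'   `p_unadjusted`, `direction`.
#' @export
correlate_score <- function(auc, scores) {
  common <- intersect(names(auc), names(scores))
  x <- scores[common]
  y <- auc[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("only ", length(x), " samples with both score and AUC (need >= 3)")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant score or AUC vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  rho <- unname(ct$estimate)
  data.frame(test = "spearman", n = length(x), effect = rho,
             p_unadjusted = ct$p.value, direction = direction_of(rho),
             stringsAsFactors = FALSE)
}

#' Holm step-down multiple-testing correction
#'
#' Standard Holm adjustment: sort p-values ascending, multiply the i-th by
#' `m - i + 1`, enforce the running maximum, cap at 1, and return the
#' adjusted values in the original input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.04 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Per-assay association analysis over a whole screen
#'
#' Runs one association mode over every assay of a screen and applies the
#' Holm correction across the family of all assays analysed in this
#' invocation (matching per-run correction families). Modes:
#' `"groups"` compares altered vs wild-type AUCs (Mann-Whitney,
#' [compare_groups()]); `"score"` correlates AUC with a per-sample score
#' (Spearman, [correlate_score()]). Assays that cannot be tested (too few
#' samples, constant vectors) are skipped and recorded in the
#' `exclusions` attribute with the reason.
#'
#' @param assays a [drug_assay_set()].
#' @param mode `"groups"` or `"score"`.
#' @param groups list with `altered` and `wt` sample-id vectors
#'   (for `mode = "groups"`; altered is group A, wild-type group B).
#' @param scores named numeric vector (for `mode = "score"`).
#' @param alpha significance level for the trend/significant flags.
#' @return data.frame with one row per tested assay: assay metadata,
#'   the test fields, `p_adjusted`, `trend` (unadjusted p < alpha) and
#'   `significant` (Holm-adjusted p < alpha); `exclusions` attribute lists
#'   skipped assays.
#' @export
associate_assays <- function(assays, mode = c("groups", "score"),
                             groups = NULL, scores = NULL, alpha = 0.05) {
  stopifnot(inherits(assays, "drug_assay_set"))
  mode <- match.arg(mode)
  if (mode == "groups" && is.null(groups)) {
    stop("mode 'groups' needs `groups` (list with altered/wt)")
  }
  if (mode == "score" && is.null(scores)) {
    stop("mode 'score' needs `scores`")
  }
  rows <- list()
  excl <- list()
  for (aid in colnames(assays$auc)) {
    auc <- assays$auc[, aid]
    names(auc) <- rownames(assays$auc)
    res <- tryCatch(
      if (mode == "groups") {
        compare_groups(auc, groups$altered, groups$wt)
      } else {
        correlate_score(auc, scores)
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      excl[[aid]] <- data.frame(assay_id = aid, reason = res,
                                stringsAsFactors = FALSE)
    } else {
      res$assay_id <- aid
      rows[[aid]] <- res
    }
  }
  results <- rbind_all(rows)
  if (is.null(results)) {
    results <- data.frame(assay_id = character(0), test = character(0),
                          effect = numeric(0), p_unadjusted = numeric(0),
                          direction = character(0), p_adjusted = numeric(0),
                          trend = logical(0), significant = logical(0))
  } else {
    results$p_adjusted <- holm_adjust(results$p_unadjusted)
    results$trend <- results$p_unadjusted < alpha
    results$significant <- results$p_adjusted < alpha
    results <- merge(assays$meta, results, by = "assay_id", sort = FALSE)
    results <- results[match(names(rows), results$assay_id), , drop = FALSE]
    rownames(results) <- NULL
  }
  attr(results, "exclusions") <- rbind_all(excl) %||%
    data.frame(assay_id = character(0), reason = character(0))
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direction-split ranked report of association results
#'
#' Reproduces the ranked layout of a screening figure: assays are split
#' into a positive panel (higher AUC with alteration/score, i.e.
#' resistance) and a negative panel (sensitivity), each ordered by
#' unadjusted p (most significant first in the positive panel, least
#' significant first in the negative panel, so the strongest effects sit
#' at the two outer ends). Per-category counts of trend and
#' Holm-significant assays are attached.
#'
#' @param results data.frame from [associate_assays()].
#' @param drug_class_filter optional character vector of categories to
#'   keep (e.g. `c("Platinum", "PARP inhibitor")`).
#' @return list with `positive`, `negative` (ordered data.frames) and
#'   `class_counts` (per-category totals of tested/trend/significant).
#' @export
summarize_panel <- function(results, drug_class_filter = NULL) {
  if (!is.null(drug_class_filter)) {
    results <- results[results$category %in% drug_class_filter, ,
                       drop = FALSE]
  }
  if (nrow(results) == 0) {
    empty <- results
    return(list(positive = empty, negative = empty,
                class_counts = data.frame(category = character(0),
                                          n_assays = integer(0),
                                          n_trend = integer(0),
                                          n_significant = integer(0))))
  }
  pos <- results[results$direction == "positive", , drop = FALSE]
  neg <- results[results$direction != "positive", , drop = FALSE]
  pos <- pos[order(pos$p_unadjusted), , drop = FALSE]
  neg <- neg[order(neg$p_unadjusted, decreasing = TRUE), , drop = FALSE]
  counts <- do.call(rbind, lapply(split(results, results$category),
    function(d) data.frame(category = d$category[1],
                           n_assays = nrow(d),
                           n_trend = sum(d$trend),
                           n_significant = sum(d$significant),
                           stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  list(positive = pos, negative = neg, class_counts = counts)
}

#' Write association results to TSV
#'
#' @param results data.frame from [associate_assays()].
#' @param path output path.
#' @export
write_association_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
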