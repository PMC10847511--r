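#' Shipped analysis configuration
#'
#' Reads the packaged YAML configuration holding the constants of the
#' annotation and association layers: the 29-gene homologous-recombination
#' panel, the 10 functional-impact predictors, the 24 drug categories, the
#' BRCA1 promoter-methylation thresholds for the two dataset dialects, and
#' the minimum altered-sample count for assay inclusion. Users may edit a
#' copy of the file and pass its path.
#'
#' @param path YAML path; defaults to the packaged
#'   `extdata/default_config.yaml`.
#' @return named list.
#' @export
default_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "hrdscreen", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' The homologous-recombination gene panel
#'
#' The 29 genes whose deleterious mutations define HR-pathway alteration.
#'
#' @param config list from [default_config()].
#' @return character vector of 29 gene symbols.
#' @export
hr_gene_panel <- function(config = default_config()) {
  as.character(config$hr_gene_panel)
}

#' @rdname hr_gene_panel
#' @export
predictor_names <- function(config = default_config()) {
  as.character(config$predictors)
}

#' @rdname hr_gene_panel
#' @export
drug_categories <- function(config = default_config()) {
  as.character(config$drug_categories)
}

norm_gene <- function(x) toupper(trimws(x))

#' Read a mutation table
#'
#' TSV with columns `sample_id`, `gene`, `variant_class` (`truncating`,
#' `missense` or `other`), `dataset_annotation`, one column per configured
#' predictor (values `deleterious`/`damaging`/`tolerated`, empty for
#' missing), `minor_cn` (minor-allele copy number at the mutated locus,
#' empty for unknown) and optionally `minor_cn_other` (the same quantity in
#' the companion dataset, used as a fallback).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  req <- c("sample_id", "gene", "variant_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Deleterious-mutation filters
#'
#' Two dataset dialects are supported. The CCLE-style filter keeps rows
#' whose dataset annotation equals the configured damaging label
#' (case-sensitive, `"damaging"` by default). The CLP-style filter keeps
#' truncating mutations unconditionally and missense mutations only when
#' every one of the 10 configured functional-impact predictors calls them
#' deleterious/damaging; a missense row with any missing predictor call
#' cannot satisfy the all-of-10 requirement and is dropped with a warning.
#'
#' @param mutations data.frame as from [read_mutation_table()].
#' @param damaging_label dataset annotation value to keep.
#' @return the retained rows.
#' @export
filter_deleterious_ccle <- function(mutations, damaging_label = "damaging") {
  keep <- !is.na(mutations$dataset_annotation) &
    mutations$dataset_annotation == damaging_label
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname filter_deleterious_ccle
#' @param predictors names of the predictor columns (default: the 10
#'   configured predictors).
#' @export
filter_deleterious_clp <- function(mutations,
                                   predictors = predictor_names()) {
  missing_cols <- setdiff(predictors, names(mutations))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  truncating <- mutations$variant_class == "truncating"
  missense <- mutations$variant_class == "missense"
  calls <- as.matrix(mutations[, predictors, drop = FALSE])
  deleterious_call <- matrix(calls %in% c("deleterious", "damaging"),
                             nrow = nrow(calls))
  all_del <- rowSums(deleterious_call) == length(predictors)
  has_missing <- rowSums(is.na(calls)) > 0
  n_dropped_missing <- sum(missense & has_missing & !all_del &
                             rowSums(!deleterious_call & !is.na(calls)) == 0)
  if (n_dropped_missing > 0) {
    warning(n_dropped_missing, " missense mutation(s) dropped because one ",
            "or more of the ", length(predictors),
            " predictor calls were missing")
  }
  keep <- truncating | (missense & all_del)
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locus-specific LOH status of a mutation
#'
#' A minor-allele copy number of 0 at the mutated locus means the wild-type
#' allele is lost (`LOH_present`); 1 or more means it is retained
#' (`LOH_absent`). When the copy number is unknown in the primary dataset,
#' the companion dataset's value is used by the same rule; if both are
#' unknown the status is `unknown` and the sample is later excluded from
#' the relevant group comparison.
#'
#' @param minor_cn integer vector (NA = unknown).
#' @param fallback_minor_cn optional companion-dataset values.
#' @return character vector in `{"LOH_present", "LOH_absent", "unknown"}`.
#' @export
annotate_loh <- function(minor_cn, fallback_minor_cn = NULL) {
  x <- as.numeric(minor_cn)
  if (!is.null(fallback_minor_cn)) {
    fb <- as.numeric(fallback_minor_cn)
    x[is.na(x)] <- fb[is.na(x)]
  }
  ifelse(is.na(x), "unknown", ifelse(x == 0, "LOH_present", "LOH_absent"))
}

#' BRCA1 promoter methylation calls
#'
#' Two dataset dialects. RRBS-style (`_ccle`): methylated iff the beta
#' values of both configured promoter regions exceed `beta_threshold`
#' (default 0.3) and the gene's expression percentile is below
#' `expr_percentile` (default 10). Array-style (`_clp`): methylated iff at
#' least `min_probes` (default 15) of the `n_probes` (default 17) promoter
#' probes satisfy beta > `beta_threshold` (default 0.2) with expression
#' percentile < `expr_percentile` (default 30). Expression percentiles are
#' ranks across the cohort (see [expression_percentile()]). Missing
#' evidence (an absent region beta, or fewer than `min_probes` probes
#' measured) yields `NA` with a warning.
#'
#' @param betas numeric vector of promoter beta values in `[0, 1]` (length
#'   2 for the RRBS rule; up to `n_probes` for the array rule).
#' @param expression_percentile the sample's expression percentile for the
#'   gene, in `[0, 100]`.
#' @param beta_threshold,expr_percentile thresholds (see above).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
call_brca1_methylation_ccle <- function(betas, expression_percentile,
                                        beta_threshold = 0.3,
                                        expr_percentile = 10) {
  if (length(betas) != 2 || anyNA(betas)) {
    warning("need beta values for both promoter regions; returning NA")
    return(NA)
  }
  if (is.na(expression_percentile)) {
    warning("missing expression percentile; returning NA")
    return(NA)
  }
  all(betas > beta_threshold) && expression_percentile < expr_percentile
}

#' @rdname call_brca1_methylation_ccle
#' @param min_probes,n_probes probe-count rule (at least `min_probes` of
#'   `n_probes` probes must qualify).
#' @export
call_brca1_methylation_clp <- function(betas, expression_percentile,
                                       beta_threshold = 0.2,
                                       expr_percentile = 30,
                                       min_probes = 15, n_probes = 17) {
  betas <- betas[!is.na(betas)]
  if (length(betas) < min_probes) {
    warning("only ", length(betas), " of ", n_probes,
            " probes measured (< ", min_probes, "); returning NA")
    return(NA)
  }
  if (is.na(expression_percentile)) {
    warning("missing expression percentile; returning NA")
    return(NA)
  }
  qualifying <- sum(betas > beta_threshold &
                      expression_percentile < expr_percentile)
  qualifying >= min_probes
}

#' Cohort expression percentiles
#'
#' Converts one gene's expression values into percentile ranks across the
#' cohort (0 = lowest, 100 = highest; average ranks for ties). "Expression
#' below 10%" then means a percentile rank below 10.
#'
#' @param x numeric expression values, one per sample.
#' @return percentiles in `[0, 100]`, same order as `x`.
#' @export
expression_percentile <- function(x) {
  100 * (rank(x, ties.method = "average", na.last = "keep") - 1) /
    (sum(!is.na(x)) - 1)
}

#' HR-pathway group assignment
#'
#' Assigns every sample to one of the five annotation groups used in the
#' downstream comparisons:
#'
#' * `BRCA_altered`: deleterious BRCA1/2 mutation with locus-specific LOH,
#'   or BRCA1 promoter methylation.
#' * `HRR_LOH_pos`: deleterious mutation in a non-BRCA panel gene with LOH.
#' * `HRR_LOH_neg`: deleterious panel-gene mutation without LOH.
#' * `WT`: no deleterious panel-gene mutation and no BRCA1 methylation.
#' * `excluded`: the only deleterious panel-gene mutations have unknown
#'   LOH status, so the sample cannot be placed.
#'
#' Mutations in genes outside the 29-gene panel never affect grouping; gene
#' symbols are matched case-insensitively after whitespace stripping.
#'
#' @param deleterious data.frame of deleterious mutations (after
#'   [filter_deleterious_ccle()]/[filter_deleterious_clp()]) with columns
#'   `sample_id`, `gene` and `loh` (from [annotate_loh()]).
#' @param methylated character vector of BRCA1-methylated sample ids.
#' @param sample_ids all cohort sample ids.
#' @param panel gene panel (default the 29 configured genes).
#' @return data.frame with `sample_id`, `group`, `brca1_methylated`.
#' @export
assign_groups <- function(deleterious, methylated, sample_ids,
                          panel = hr_gene_panel()) {
  panel <- norm_gene(panel)
  in_panel <- norm_gene(deleterious$gene) %in% panel
  g <- norm_gene(deleterious$gene[in_panel])
  sid <- deleterious$sample_id[in_panel]
  loh <- deleterious$loh[in_panel]
  brca <- c("BRCA1", "BRCA2")
  has <- function(cond) sample_ids %in% unique(sid[cond])
  brca_loh <- has(g %in% brca & loh == "LOH_present")
  any_loh <- has(loh == "LOH_present")
  any_no_loh <- has(loh == "LOH_absent")
  any_mut <- sample_ids %in% unique(sid)
  meth <- sample_ids %in% methylated
  group <- ifelse(meth | brca_loh, "BRCA_altered",
           ifelse(!any_mut, "WT",
           ifelse(any_loh, "HRR_LOH_pos",
           ifelse(any_no_loh, "HRR_LOH_neg", "excluded"))))
  data.frame(sample_id = sample_ids, group = unname(group),
             brca1_methylated = sample_ids %in% methylated,
             stringsAsFactors = FALSE)
}

#' Two-group comparison sets from annotations
#'
#' Derives the altered/wild-type sample sets for the two comparison
#' schemes. `brca_vs_wt` compares `BRCA_altered` samples against `WT`;
#' samples in any other group are excluded. `hrr_vs_wt` compares samples
#' with any HR-pathway alteration against `WT`: with
#' `require_loh_for_hrr = TRUE` (default) the altered set is
#' `BRCA_altered` plus `HRR_LOH_pos`; with `FALSE` it additionally
#' includes `HRR_LOH_neg`. The `WT` set is identical across schemes, and
#' the `brca_vs_wt` altered set is always a subset of the `hrr_vs_wt`
#' altered set.
#'
#' @param annotations data.frame from [assign_groups()].
#' @param scheme `"brca_vs_wt"` or `"hrr_vs_wt"`.
#' @param require_loh_for_hrr whether non-BRCA mutations must show LOH to
#'   count as altered in the `hrr_vs_wt` scheme.
#' @return list with character vectors `altered` and `wt`.
#' @export
comparison_groups <- function(annotations,
                              scheme = c("brca_vs_wt", "hrr_vs_wt"),
                              require_loh_for_hrr = TRUE) {
  scheme <- match.arg(scheme)
  altered_groups <- if (scheme == "brca_vs_wt") "BRCA_altered" else {
    c("BRCA_altered", "HRR_LOH_pos",
      if (!require_loh_for_hrr) "HRR_LOH_neg")
  }
  list(
    altered = annotations$sample_id[annotations$group %in% altered_groups],
    wt = annotations$sample_id[annotations$group == "WT"]
  )
}

#' Write per-sample annotations to TSV
#'
#' @param annotations data.frame from [assign_groups()] (possibly merged
#'   with scores).
#' @param path output path.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
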