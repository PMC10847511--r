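#' Analyse a cohort in memory
#'
#' Runs the full analysis over an assembled cohort: scar scoring of every
#' segment profile, SBS96 spectra and signature-3 cosine similarity,
#' deleterious-mutation filtering with locus-specific LOH and BRCA1
#' methylation calls, HR-pathway group assignment, assay filtering, and
#' the four association analyses (BRCA-altered vs wild-type and
#' HR-altered vs wild-type Mann-Whitney comparisons; Spearman correlation
#' of AUC with the HRD score and with signature 3), each Holm-corrected
#' within its own family.
#'
#' @param cohort an `hrd_cohort` from [simulate_cohort()] or
#'   [read_cohort_dir()].
#' @param scar a [scar_config()].
#' @param alpha significance level for trend/significant flags.
#' @param min_altered minimum altered samples per assay
#'   (see [filter_assays()]).
#' @param require_loh_for_hrr see [comparison_groups()].
#' @param mutation_dialect `"ccle"` (dataset-annotation filter) or
#'   `"clp"` (truncating / all-predictors-deleterious filter).
#' @return list with `scores`, `signature3`, `annotations` (per-sample
#'   table incl. scores), `groups`, `associations` (named list of result
#'   tables), and `exclusions`.
#' @export
analyze_cohort <- function(cohort, scar = scar_config(), alpha = 0.05,
                           min_altered = 10, require_loh_for_hrr = TRUE,
                           mutation_dialect = c("ccle", "clp")) {
  mutation_dialect <- match.arg(mutation_dialect)
  scores <- score_cohort(cohort$profiles, cohort$genome, scar)

  spectra <- build_spectra(cohort$snvs)
  sig_tab <- signature_cosine_table(spectra)

  deleterious <- if (mutation_dialect == "ccle") {
    filter_deleterious_ccle(cohort$mutations)
  } else {
    filter_deleterious_clp(cohort$mutations)
  }
  deleterious$loh <- annotate_loh(
    deleterious$minor_cn,
    if ("minor_cn_other" %in% names(deleterious)) {
      deleterious$minor_cn_other
    }
  )
  expr_pct <- stats::setNames(
    expression_percentile(cohort$expression$BRCA1),
    cohort$expression$sample_id)
  beta_cols <- setdiff(names(cohort$methylation), "sample_id")
  betas <- as.matrix(cohort$methylation[, beta_cols, drop = FALSE])
  pct <- expr_pct[cohort$methylation$sample_id]
  meth_call <- vapply(seq_len(nrow(betas)), function(i) {
    isTRUE(call_brca1_methylation_ccle(betas[i, ], pct[[i]]))
  }, logical(1))
  methylated <- cohort$methylation$sample_id[meth_call]

  ids <- scores$sample_id
  annotations <- assign_groups(deleterious, methylated, ids)
  annotations <- merge(annotations, scores, by = "sample_id", sort = FALSE)
  annotations <- merge(annotations,
                       sig_tab[, c("sample_id", "n_snvs",
                                   "signature3_cosine")],
                       by = "sample_id", all.x = TRUE, sort = FALSE)

  grp_brca <- comparison_groups(annotations, "brca_vs_wt")
  grp_hrr <- comparison_groups(annotations, "hrr_vs_wt",
                               require_loh_for_hrr = require_loh_for_hrr)
  assays <- filter_assays(cohort$assays, grp_hrr$altered, min_altered)
  hrd_scores <- stats::setNames(scores$hrd_score, scores$sample_id)
  sig3_scores <- stats::setNames(annotations$signature3_cosine,
                                 annotations$sample_id)
  associations <- list(
    brca_groups = associate_assays(assays, "groups", groups = grp_brca,
                                   alpha = alpha),
    hrr_groups = associate_assays(assays, "groups", groups = grp_hrr,
                                  alpha = alpha),
    hrd_score = associate_assays(assays, "score", scores = hrd_scores,
                                 alpha = alpha),
    signature3 = associate_assays(assays, "score",
                                  scores = sig3_scores[!is.na(sig3_scores)],
                                  alpha = alpha)
  )
  excl_tagged <- function(stage, ex) {
    if (is.null(ex) || nrow(ex) == 0) return(NULL)
    cbind(stage = stage, ex)
  }
  exclusions <- rbind(
    excl_tagged("assay_filter", attr(assays, "exclusions")),
    do.call(rbind, lapply(names(associations), function(nm) {
      excl_tagged(nm, attr(associations[[nm]], "exclusions"))
    }))
  )
  list(scores = scores, signature3 = sig_tab, annotations = annotations,
       groups = list(brca_vs_wt = grp_brca, hrr_vs_wt = grp_hrr),
       associations = associations,
       exclusions = exclusions %||%
         data.frame(stage = character(0), assay_id = character(0),
                    reason = character(0)))
}

#' Read a cohort from a directory of standard tables
#'
#' Ingests the file dialects written by [write_cohort()] (or prepared by
#' the user): `arms.tsv`, `segments.tsv`, `snvs.tsv`, `mutations.tsv`,
#' `methylation.csv`, `expression.csv`, `assay_meta.csv`, `auc.csv`.
#'
#' @param dir directory path.
#' @return an `hrd_cohort` (without ground-truth ledger).
#' @export
read_cohort_dir <- function(dir) {
  p <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      stop("missing input file for stage '", f, "': ", path)
    }
    path
  }
  genome <- read_arm_table(p("arms.tsv"))
  profiles <- read_segment_table(p("segments.tsv"), genome)
  segments <- rbind_all(lapply(profiles, as.data.frame))
  structure(list(
    segments = segments, profiles = profiles,
    snvs = read_snv_table(p("snvs.tsv")),
    mutations = read_mutation_table(p("mutations.tsv")),
    methylation = utils::read.csv(p("methylation.csv"),
                                  stringsAsFactors = FALSE),
    expression = utils::read.csv(p("expression.csv"),
                                 stringsAsFactors = FALSE),
    assays = read_assay_set(p("assay_meta.csv"), p("auc.csv")),
    ledger = NULL, genome = genome, config = NULL
  ), class = "hrd_cohort")
}

#' Run the end-to-end pipeline
#'
#' Simulates or ingests a cohort, analyses it ([analyze_cohort()]), writes
#' every stage output as TSV under `out_dir`, and records a YAML run
#' manifest with the configuration and an MD5 checksum of every output
#' file. Re-running with the same configuration and seed reproduces the
#' outputs bit for bit.
#'
#' @param out_dir output directory.
#' @param input_dir directory of input tables ([read_cohort_dir()]);
#'   ignored when `simulate` is given.
#' @param simulate optional [cohort_config()]; when supplied the cohort is
#'   simulated and its ground truth written alongside the results.
#' @inheritParams analyze_cohort
#' @return the [analyze_cohort()] result, invisibly, with a `manifest`
#'   element.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL, simulate = NULL,
                         scar = scar_config(), alpha = 0.05,
                         min_altered = 10, require_loh_for_hrr = TRUE,
                         mutation_dialect = "ccle") {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("supply either input_dir or a simulation config")
  }
  cohort <- if (!is.null(simulate)) simulate_cohort(simulate) else
    read_cohort_dir(input_dir)
  res <- analyze_cohort(cohort, scar = scar, alpha = alpha,
                        min_altered = min_altered,
                        require_loh_for_hrr = require_loh_for_hrr,
                        mutation_dialect = mutation_dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_scar_table(res$scores, p("scar_scores.tsv"))
  write_signature_table(res$signature3, p("signature3.tsv"))
  write_annotation_table(res$annotations, p("annotations.tsv"))
  for (nm in names(res$associations)) {
    write_association_table(res$associations[[nm]],
                            p(sprintf("associations_%s.tsv", nm)))
  }
  utils::write.table(res$exclusions, p("exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$ledger)) {
    utils::write.table(cohort$ledger, p("ledger.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  # ranked per-class summary mirroring the direction-split figures
  report <- lapply(res$associations, summarize_panel)
  summary_rows <- do.call(rbind, lapply(names(report), function(nm) {
    cc <- report[[nm]]$class_counts
    if (nrow(cc) == 0) return(NULL)
    cbind(analysis = nm, cc)
  }))
  if (!is.null(summary_rows)) {
    utils::write.table(summary_rows, p("class_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, p("manifest.yaml"))
  manifest <- list(
    package = "hrdscreen",
    settings = list(alpha = alpha, min_altered = min_altered,
                    require_loh_for_hrr = require_loh_for_hrr,
                    mutation_dialect = mutation_dialect,
                    scar = unclass(scar),
                    seed = if (!is.null(simulate)) simulate$seed),
    checksums = as.list(tools::md5sum(outputs))
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  res$manifest <- manifest
  res$report <- report
  invisible(res)
}
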