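#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cell-line cohort generator. Each sample has
#' a latent HRD (homologous-recombination-deficient) status that drives
#' every emitted data type: scar-event counts on the copy-number profile,
#' the signature-3 mixture weight of its SNV catalog, the chance of BRCA1
#' promoter methylation, the HR-gene mutation table, and a configurable
#' AUC shift in the affected drug classes.
#'
#' Scar events are planted by an event grammar that constructs each event
#' to satisfy its counting rule exactly and isolates events with buffers
#' wider than the LST smoothing scale, so the planted counts are exact
#' ground truth, not approximations (see the ground-truth ledger).
#'
#' @param n_samples cohort size.
#' @param hrd_prevalence probability a sample is HRD-positive.
#' @param scar_rates_pos,scar_rates_neg named numeric vectors
#'   `c(tai=, lst=, loh=)` of Poisson means for the per-sample planted
#'   event counts in HRD-positive / HRD-negative samples.
#' @param n_snvs_mean,snv_dispersion negative-binomial mean and size of
#'   the per-sample SNV count.
#' @param sig3_weight_pos,sig3_weight_neg signature-3 mixture weight of
#'   the SNV catalog for HRD-positive / negative samples.
#' @param methylation_rate probability an HRD-positive sample carries
#'   BRCA1 promoter methylation (instead of a mutation mechanism).
#' @param brca_fraction among mutation-driven HRD-positive samples, the
#'   probability the mutated gene is BRCA1/2 (vs another panel gene).
#' @param hrr_loh_neg_rate probability an HRD-negative sample carries a
#'   deleterious panel-gene mutation without LOH.
#' @param passenger_rate probability of an extra deleterious mutation in a
#'   non-panel gene (never affects grouping).
#' @param unknown_cn_rate fraction of mutations whose minor-allele copy
#'   number is only available in the companion dataset (exercises the
#'   cross-dataset LOH fallback).
#' @param assay_categories drug classes to simulate.
#' @param n_assays_per_class assays per class.
#' @param affected_classes classes whose AUC responds to the HRD score.
#' @param auc_effect AUC shift in units of `auc_noise_sd` per standard
#'   deviation of HRD score; positive means higher score brings resistance
#'   (higher AUC), negative means sensitivity.
#' @param auc_noise_sd,auc_baseline Gaussian AUC noise SD and intercept.
#' @param auc_missing_rate fraction of AUC entries set missing.
#' @param genome [arm_table()] the profiles live on; the default is a
#'   toy genome large enough that Poisson-drawn event counts essentially
#'   always fit.
#' @param scar [scar_config()] whose thresholds the planted events are
#'   constructed against.
#' @param signatures reference signature matrix for the SNV mixture.
#' @param sig3_name,background_sig_name mixture component names.
#' @param seed integer seed; fixes the whole cohort bit-for-bit.
#' @return named list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200,
                          hrd_prevalence = 0.3,
                          scar_rates_pos = c(tai = 1.5, lst = 1.5, loh = 2),
                          scar_rates_neg = c(tai = 0.3, lst = 0.3, loh = 0.3),
                          n_snvs_mean = 200,
                          snv_dispersion = 5,
                          sig3_weight_pos = 0.7,
                          sig3_weight_neg = 0.1,
                          methylation_rate = 0.2,
                          brca_fraction = 0.6,
                          hrr_loh_neg_rate = 0.1,
                          passenger_rate = 0.2,
                          unknown_cn_rate = 0.1,
                          assay_categories = c("Platinum", "PARP inhibitor",
                                               "Topoisomerase inhibitor",
                                               "Antimetabolite"),
                          n_assays_per_class = 5,
                          affected_classes = c("Platinum", "PARP inhibitor"),
                          auc_effect = 0.5,
                          auc_noise_sd = 0.1,
                          auc_baseline = 0.6,
                          auc_missing_rate = 0.02,
                          genome = toy_genome(8),
                          scar = scar_config(),
                          signatures = NULL,
                          sig3_name = "Signature 3",
                          background_sig_name = "Signature 1",
                          seed = 1) {
  probs <- c(hrd_prevalence, sig3_weight_pos, sig3_weight_neg,
             methylation_rate, brca_fraction, hrr_loh_neg_rate,
             passenger_rate, unknown_cn_rate, auc_missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(scar_rates_pos >= 0), all(scar_rates_neg >= 0),
            n_samples >= 1, n_snvs_mean >= 0, auc_noise_sd > 0,
            inherits(genome, "arm_table"), inherits(scar, "scar_config"))
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

# Deterministic sub-stream seeds: one stream per data type, so adding
# assays never perturbs the segment simulation.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L + stage * 97L
}

# --- scar-event grammar -----------------------------------------------------

# One arm per row: chromosome, lo/hi bounds, which side the telomere is on.
arm_frame <- function(genome) {
  rbind(
    data.frame(chromosome = genome$chromosome, lo = 1,
               hi = genome$centromere_start - 1, side = "left",
               stringsAsFactors = FALSE),
    data.frame(chromosome = genome$chromosome, lo = genome$centromere_end + 1,
               hi = genome$chrom_length, side = "right",
               stringsAsFactors = FALSE)
  )
}

# Plant exactly n_tai / n_lst / n_loh qualifying events for one sample.
# Every event is isolated by > smooth_len uncovered buffer, so no
# incidental TAI/LST/LOH events can arise. Works on plain vectors for
# speed; pieces of one event are ordered from the telomere inward.
plant_events <- function(n_tai, n_lst, n_loh, arms_f, sizes) {
  n_arms <- nrow(arms_f)
  if (n_tai > n_arms) {
    stop("infeasible event packing: ", n_tai, " telomeric events but only ",
         n_arms, " arms; use a larger genome or lower scar rates")
  }
  lo <- arms_f$lo; hi <- arms_f$hi; left <- arms_f$side == "left"
  arm_len <- hi - lo + 1
  # per-placed-piece accumulators
  arm_i <- integer(0); off_s <- numeric(0); off_e <- numeric(0)
  tot <- numeric(0); bcn <- numeric(0)
  add_piece <- function(a, s, e, t, b) {
    arm_i[length(arm_i) + 1] <<- a
    off_s[length(off_s) + 1] <<- s
    off_e[length(off_e) + 1] <<- e
    tot[length(tot) + 1] <<- t
    bcn[length(bcn) + 1] <<- b
  }
  cursor <- rep(sizes$gap, n_arms)              # leading buffer
  tai_arms <- if (n_tai > 0) sample.int(n_arms, n_tai) else integer(0)
  for (a in tai_arms) {
    add_piece(a, 0, sizes$tai_len - 1, 3, 1)    # (3,2,1): imbalanced
    cursor[a] <- sizes$tai_len + sizes$gap
  }
  events <- sample(rep(c("lst", "loh"), c(n_lst, n_loh)))
  for (ev in events) {
    need <- if (ev == "lst") 2 * sizes$lst_seg else sizes$loh_len
    ok <- which(cursor + need <= arm_len)
    if (length(ok) == 0) {
      stop("infeasible event packing: no arm can hold a ", ev,
           " event; use a larger genome or lower scar rates")
    }
    a <- ok[sample.int(length(ok), 1)]
    if (ev == "lst") {                          # (2,1,1) | (4,2,2) junction
      add_piece(a, cursor[a], cursor[a] + sizes$lst_seg - 1, 2, 1)
      add_piece(a, cursor[a] + sizes$lst_seg,
                cursor[a] + 2 * sizes$lst_seg - 1, 4, 2)
    } else {                                    # (1,1,0): long LOH
      add_piece(a, cursor[a], cursor[a] + sizes$loh_len - 1, 1, 0)
    }
    cursor[a] <- cursor[a] + need + sizes$gap
  }
  # balanced diploid background on the unused inner part of each arm
  for (a in seq_len(n_arms)) {
    if (arm_len[a] - cursor[a] < 1) next
    add_piece(a, cursor[a], arm_len[a] - 1, 2, 1)
  }
  # telomere-local offsets -> genomic coordinates
  start <- ifelse(left[arm_i], lo[arm_i] + off_s, hi[arm_i] - off_e)
  end <- ifelse(left[arm_i], lo[arm_i] + off_e, hi[arm_i] - off_s)
  data.frame(chromosome = arms_f$chromosome[arm_i], start = start,
             end = end, total_cn = tot, a_cn = tot - bcn, b_cn = bcn,
             stringsAsFactors = FALSE)
}

# --- full cohort ------------------------------------------------------------

#' Simulate a complete synthetic cohort
#'
#' Generates, under a single seed, every input the analysis pipeline
#' consumes - allele-specific segment profiles, SNV catalogs with inline
#' trinucleotide contexts, an HR-gene mutation table with predictor calls
#' and minor-allele copy numbers, BRCA1 promoter methylation and
#' expression values, and per-assay AUC matrices - together with a
#' ground-truth ledger of the planted quantities. The planted scar-event
#' counts are exact: scoring the emitted segments recovers the ledger
#' counts identically (the central simulator-scorer oracle).
#'
#' @param config a [cohort_config()].
#' @return list of class `hrd_cohort` with elements `segments`,
#'   `profiles`, `snvs`, `mutations`, `methylation`, `expression`,
#'   `assays` (a [drug_assay_set()]), `ledger`, `assay_truth`, `genome`
#'   and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sigs <- config$signatures
  if (is.null(sigs)) sigs <- synthetic_signature_set()
  ids <- sprintf("CL%04d", seq_len(config$n_samples))
  arms_f <- arm_frame(config$genome)
  sizes <- list(tai_len = config$scar$tai_min_len + 1e6,
                loh_len = config$scar$loh_min_len + 1e6,
                lst_seg = config$scar$lst_min_seg + 2e6,
                gap = config$scar$lst_smooth_len + 2e6)

  # stage 1: HRD status and planted scar-event counts
  set.seed(stage_seed(config$seed, 1L))
  hrd <- stats::rbinom(config$n_samples, 1, config$hrd_prevalence) == 1
  rate <- function(comp) {
    ifelse(hrd, config$scar_rates_pos[[comp]], config$scar_rates_neg[[comp]])
  }
  n_tai <- stats::rpois(config$n_samples, rate("tai"))
  n_lst <- stats::rpois(config$n_samples, rate("lst"))
  n_loh <- stats::rpois(config$n_samples, rate("loh"))
  seg_list <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    seg <- plant_events(n_tai[i], n_lst[i], n_loh[i], arms_f, sizes)
    seg <- cbind(sample_id = ids[i], seg, stringsAsFactors = FALSE)
    seg_list[[i]] <- seg[order(seg$chromosome, seg$start), ]
  }
  segments <- rbind_all(seg_list)
  # generator-built segments satisfy the profile invariants by
  # construction, so skip revalidation (read_segment_table() still
  # validates everything that comes back off disk)
  profiles <- lapply(seg_list, function(s) {
    rownames(s) <- NULL
    new_segment_profile(s[, seg_columns], s$sample_id[1])
  })
  names(profiles) <- ids

  # stage 2: SNV catalogs from the signature mixture
  set.seed(stage_seed(config$seed, 2L))
  w <- ifelse(hrd, config$sig3_weight_pos, config$sig3_weight_neg)
  p3 <- sigs[, config$sig3_name]
  p1 <- sigs[, config$background_sig_name]
  channels <- sbs96_channels()
  n_snv <- stats::rnbinom(config$n_samples, size = config$snv_dispersion,
                          mu = config$n_snvs_mean)
  ch_list <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    if (n_snv[i] == 0) next
    cnt <- stats::rmultinom(1, n_snv[i], w[i] * p3 + (1 - w[i]) * p1)[, 1]
    ch_list[[i]] <- rep(channels, cnt)
  }
  ch <- unlist(ch_list)
  ref <- substr(ch, 3, 3); alt <- substr(ch, 5, 5)
  ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
  flip <- stats::runif(length(ch)) < 0.5     # emitted on the purine strand
  ctx[flip] <- revcomp3(ctx[flip])
  ref[flip] <- comp_base(ref[flip]); alt[flip] <- comp_base(alt[flip])
  chrom <- sample(config$genome$chromosome, length(ch), replace = TRUE)
  maxpos <- config$genome$chrom_length[match(chrom, config$genome$chromosome)]
  snvs <- data.frame(
    sample_id = rep(ids, n_snv), chromosome = chrom,
    position = floor(stats::runif(length(ch), 2, maxpos - 1)),
    ref = ref, alt = alt, context = ctx, stringsAsFactors = FALSE)

  # stage 3: HR-gene alterations, methylation, expression
  set.seed(stage_seed(config$seed, 3L))
  panel <- hr_gene_panel()
  non_brca <- setdiff(panel, c("BRCA1", "BRCA2"))
  mechanism <- rep("none", config$n_samples)
  u <- stats::runif(config$n_samples)
  v <- stats::runif(config$n_samples)
  mechanism[hrd] <- ifelse(u[hrd] < config$methylation_rate, "methylation",
                           ifelse(v[hrd] < config$brca_fraction,
                                  "brca_mutation", "hrr_mutation"))
  mechanism[!hrd & u < config$hrr_loh_neg_rate] <- "hrr_no_loh"
  preds <- predictor_names()
  mut_tab <- function(sid, gene, cn, damaging) {
    n <- length(sid)
    if (n == 0) return(NULL)
    df <- data.frame(
      sample_id = sid, gene = gene,
      variant_class = if (damaging) {
        ifelse(stats::runif(n) < 0.5, "truncating", "missense")
      } else "other",
      dataset_annotation = if (damaging) "damaging" else "silent",
      stringsAsFactors = FALSE)
    for (p in preds) df[[p]] <- if (damaging) "deleterious" else "tolerated"
    unknown <- damaging & stats::runif(n) < config$unknown_cn_rate
    df$minor_cn <- ifelse(unknown, NA_real_, cn)
    df$minor_cn_other <- cn
    df
  }
  i_brca <- which(mechanism == "brca_mutation")
  i_hrr <- which(mechanism == "hrr_mutation")
  i_neg <- which(mechanism == "hrr_no_loh")
  i_pass <- which(stats::runif(config$n_samples) < config$passenger_rate)
  # a silent panel-gene row the deleteriousness filter must drop
  i_silent <- which(stats::runif(config$n_samples) < 0.3)
  pick <- function(pool, n) sample(pool, n, replace = TRUE)
  mutations <- rbind(
    mut_tab(ids[i_brca], pick(c("BRCA1", "BRCA2"), length(i_brca)),
            0, TRUE),
    mut_tab(ids[i_hrr], pick(non_brca, length(i_hrr)), 0, TRUE),
    mut_tab(ids[i_neg], pick(non_brca, length(i_neg)),
            pick(1:2, length(i_neg)), TRUE),
    mut_tab(ids[i_pass], pick(c("TP53", "KRAS", "PTEN", "EGFR"),
                              length(i_pass)),
            pick(0:2, length(i_pass)), TRUE),
    mut_tab(ids[i_silent], pick(panel, length(i_silent)),
            pick(0:2, length(i_silent)), FALSE),
    make.row.names = FALSE)
  if (is.null(mutations)) {
    mutations <- mut_tab("dummy", "GENE", 0, TRUE)[0, , drop = FALSE]
  }
  mutations <- mutations[order(mutations$sample_id), , drop = FALSE]
  rownames(mutations) <- NULL
  methylated <- mechanism == "methylation"
  methylation <- data.frame(
    sample_id = ids,
    promoter_region_1 = ifelse(methylated, stats::runif(config$n_samples,
                                                        0.45, 0.95),
                               stats::runif(config$n_samples, 0.01, 0.25)),
    promoter_region_2 = ifelse(methylated, stats::runif(config$n_samples,
                                                        0.45, 0.95),
                               stats::runif(config$n_samples, 0.01, 0.25)),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    sample_id = ids,
    BRCA1 = ifelse(methylated, stats::runif(config$n_samples, 0, 1),
                   stats::runif(config$n_samples, 5, 100)),
    stringsAsFactors = FALSE)

  # stage 4: drug-response AUC matrices
  set.seed(stage_seed(config$seed, 4L))
  hrd_score <- n_tai + n_lst + n_loh
  z <- if (stats::sd(hrd_score) > 0) {
    (hrd_score - mean(hrd_score)) / stats::sd(hrd_score)
  } else {
    rep(0, config$n_samples)
  }
  drug_pool <- list(
    "Platinum" = c("Cisplatin", "Carboplatin", "Oxaliplatin"),
    "PARP inhibitor" = c("Olaparib", "Talazoparib", "Niraparib", "Rucaparib",
                         "Veliparib"))
  sources <- c("GDSC1", "GDSC2", "CTRP2", "PRISM", "gCSI")
  meta_rows <- list()
  k <- 0L
  for (cls in config$assay_categories) {
    pool <- drug_pool[[cls]] %||% paste0(gsub("[^A-Za-z]", "", cls), "-drug")
    for (j in seq_len(config$n_assays_per_class)) {
      k <- k + 1L
      drug <- pool[(j - 1) %% length(pool) + 1]
      meta_rows[[k]] <- data.frame(
        assay_id = sprintf("%s %d", drug, (j - 1) %/% length(pool) + 1),
        drug_name = drug, compound_id = sprintf("CID%05d", 10000 + k),
        source = sources[(k - 1) %% length(sources) + 1],
        category = cls, stringsAsFactors = FALSE)
    }
  }
  meta <- rbind_all(meta_rows)
  affected <- meta$category %in% config$affected_classes
  auc <- matrix(NA_real_, config$n_samples, nrow(meta),
                dimnames = list(ids, meta$assay_id))
  for (a in seq_len(nrow(meta))) {
    shift <- if (affected[a]) {
      config$auc_effect * config$auc_noise_sd * z
    } else 0
    auc[, a] <- config$auc_baseline + shift +
      stats::rnorm(config$n_samples, 0, config$auc_noise_sd)
  }
  if (config$auc_missing_rate > 0) {
    auc[stats::runif(length(auc)) < config$auc_missing_rate] <- NA_real_
  }
  assays <- suppressWarnings(drug_assay_set(meta, auc))

  truth_group <- c(none = "WT", methylation = "BRCA_altered",
                   brca_mutation = "BRCA_altered",
                   hrr_mutation = "HRR_LOH_pos",
                   hrr_no_loh = "HRR_LOH_neg")[mechanism]
  ledger <- data.frame(
    sample_id = ids, hrd = hrd, tai = n_tai, lst = n_lst, loh = n_loh,
    hrd_score = hrd_score, sig3_weight = w, n_snvs = n_snv,
    mechanism = mechanism, methylated = methylated,
    group = unname(truth_group), stringsAsFactors = FALSE)
  assay_truth <- data.frame(assay_id = meta$assay_id,
                            category = meta$category, affected = affected,
                            auc_effect = ifelse(affected, config$auc_effect,
                                                0),
                            stringsAsFactors = FALSE)
  structure(list(segments = segments, profiles = profiles, snvs = snvs,
                 mutations = mutations, methylation = methylation,
                 expression = expression, assays = assays, ledger = ledger,
                 assay_truth = assay_truth, genome = config$genome,
                 config = config),
            class = "hrd_cohort")
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat(sprintf(paste0("<hrd_cohort> %d samples (%d HRD+), %d segments, ",
                     "%d SNVs, %d assays\n"),
              nrow(x$ledger), sum(x$ledger$hrd), nrow(x$segments),
              nrow(x$snvs), ncol(x$assays$auc)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes every table in exactly the dialect the corresponding reader
#' consumes: `segments.tsv` ([read_segment_table()]), `snvs.tsv`
#' ([read_snv_table()]), `mutations.tsv` ([read_mutation_table()]),
#' `methylation.csv` / `expression.csv`, `assay_meta.csv` / `auc.csv`
#' ([read_assay_set()]), `arms.tsv` ([read_arm_table()]) and the
#' ground-truth `ledger.tsv` / `assay_truth.tsv`.
#'
#' @param cohort an `hrd_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_segment_table(cohort$profiles, p("segments.tsv"))
  utils::write.table(cohort$snvs, p("snvs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$mutations, p("mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$methylation, p("methylation.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$expression, p("expression.csv"), row.names = FALSE)
  utils::write.csv(cohort$assays$meta, p("assay_meta.csv"),
                   row.names = FALSE)
  aucdf <- data.frame(sample_id = rownames(cohort$assays$auc),
                      cohort$assays$auc, check.names = FALSE)
  utils::write.csv(aucdf, p("auc.csv"), row.names = FALSE)
  arms_out <- cohort$genome
  utils::write.table(arms_out, p("arms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$ledger, p("ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$assay_truth, p("assay_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Family-wise error of the pipeline under the null
#'
#' Validation harness for the association layer: simulates `n_replicates`
#' cohorts with no drug-response effect (`auc_effect = 0`), pushes each
#' through the analysis stages (scar scoring, spectra, annotation,
#' score-AUC association with Holm correction), and reports the fraction
#' of replicate families containing any Holm-significant assay (the
#' family-wise error) together with the pooled per-test type-I error.
#'
#' @param config a [cohort_config()] with `auc_effect = 0`.
#' @param n_replicates number of replicate cohorts (>= 1).
#' @param alpha significance level.
#' @return list: `fwer`, `type1_rate`, `n_replicates`, `n_tests`,
#'   `fwer_se` (binomial Monte-Carlo SE), `pvalues`.
#' @export
simulate_null_family <- function(config, n_replicates, alpha = 0.05) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (config$auc_effect != 0) {
    stop("simulate_null_family requires auc_effect = 0")
  }
  any_sig <- logical(n_replicates)
  pvals <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- stage_seed(config$seed, 100L + r)
    cohort <- simulate_cohort(cfg)
    res <- analyze_cohort(cohort, alpha = alpha)
    assoc <- res$associations$hrd_score
    any_sig[r] <- any(assoc$significant)
    pvals[[r]] <- assoc$p_unadjusted
  }
  pv <- unlist(pvals)
  fwer <- mean(any_sig)
  list(fwer = fwer, type1_rate = mean(pv < alpha),
       n_replicates = n_replicates, n_tests = length(pv),
       fwer_se = sqrt(fwer * (1 - fwer) / n_replicates), pvalues = pv)
}
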