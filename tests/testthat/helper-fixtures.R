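# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk except files the tests write themselves.

toy3 <- toy_genome()   # 3 x 100 Mb, centromere 45-55 Mb

# Quick profile constructor: seg(chromosome, start, end, total, a, b) rows.
make_profile <- function(..., sample_id = "S1", arms = toy3) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("start", "end", "total_cn", "a_cn", "b_cn")
  df$chromosome <- vapply(rows, function(r) attr(r, "chrom"), character(1))
  df$sample_id <- sample_id
  segment_profile(df, arms)
}

seg <- function(chrom, start, end, total, a, b) {
  structure(c(start = start, end = end, total_cn = total, a_cn = a,
              b_cn = b), chrom = chrom)
}

# A fully balanced diploid genome on the toy arms.
balanced_profile <- function(sample_id = "S0", arms = toy3) {
  df <- data.frame(sample_id = sample_id, chromosome = arms$chromosome,
                   start = 1, end = arms$chrom_length,
                   total_cn = 2, a_cn = 1, b_cn = 1)
  segment_profile(df, arms)
}

# Random segment profiles exercising all rule edges: short/long segments,
# balanced/imbalanced/LOH states, gaps, telomere- and centromere-touching
# placements, and occasional whole-chromosome LOH.
random_profile <- function(arms = toy3, sample_id = "R1") {
  states <- list(c(2, 1, 1), c(1, 1, 0), c(3, 2, 1), c(4, 2, 2),
                 c(2, 2, 0), c(3, 3, 0), c(0, 0, 0), c(2, 2, 0))
  rows <- list()
  for (ci in seq_len(nrow(arms))) {
    chrom <- arms$chromosome[ci]
    clen <- arms$chrom_length[ci]
    if (runif(1) < 0.05) {   # whole-chromosome LOH, sometimes split in two
      if (runif(1) < 0.5) {
        rows[[length(rows) + 1]] <- data.frame(
          chromosome = chrom, start = 1, end = clen,
          total_cn = 1, a_cn = 1, b_cn = 0)
      } else {
        cut <- floor(runif(1, 0.2, 0.8) * clen)
        rows[[length(rows) + 1]] <- data.frame(
          chromosome = chrom, start = c(1, cut + 1), end = c(cut, clen),
          total_cn = c(1, 2), a_cn = c(1, 2), b_cn = c(0, 0))
      }
      next
    }
    pos <- 1
    while (pos < clen - 1e6) {
      gap <- if (runif(1) < 0.55) 0 else floor(runif(1, 1, 8e6))
      start <- pos + gap
      if (start >= clen) break
      len <- floor(exp(runif(1, log(5e5), log(4e7))))
      end <- min(start + len - 1, clen)
      st <- states[[sample.int(length(states), 1)]]
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = chrom, start = start, end = end,
        total_cn = st[1], a_cn = st[2], b_cn = st[3])
      pos <- end + 1
    }
  }
  df <- do.call(rbind, rows)
  df$sample_id <- sample_id
  segment_profile(df, arms)
}

# Minimal mutation-table row with all predictor columns populated.
mut_row <- function(sample_id, gene, variant_class = "truncating",
                    dataset_annotation = "damaging",
                    predictor_call = "deleterious", minor_cn = 0,
                    minor_cn_other = NA) {
  df <- data.frame(sample_id = sample_id, gene = gene,
                   variant_class = variant_class,
                   dataset_annotation = dataset_annotation,
                   stringsAsFactors = FALSE)
  for (p in predictor_names()) df[[p]] <- predictor_call
  df$minor_cn <- minor_cn
  df$minor_cn_other <- minor_cn_other
  df
}
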