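#' Scar-score configuration
#'
#' The three genomic scar components are counting rules over allele-specific
#' segments; all their length constants are exposed here and default to the
#' conventional values used by scarHRD-style pipelines:
#'
#' * `loh_min_len` (15 Mb): a loss-of-heterozygosity region must exceed this
#'   length to count, and must not span an entire chromosome.
#' * `tai_min_len` (11 Mb): minimum length of a telomeric allelic-imbalance
#'   segment.
#' * `lst_min_seg` (10 Mb): both segments flanking a large-scale state
#'   transition must be at least this long (after smoothing).
#' * `lst_smooth_len` (3 Mb): segments shorter than this are removed before
#'   transition counting, and a transition's inter-segment gap must not
#'   exceed it.
#' * `telomere_tolerance` (0 bp): how far from base 1 / the chromosome end a
#'   segment may start/stop and still be considered telomere-touching;
#'   useful because real segment tables rarely reach literal base 1.
#'
#' @param loh_min_len,tai_min_len,lst_min_seg,lst_smooth_len,telomere_tolerance
#'   lengths in bp (see above).
#' @return a named list of class `scar_config`.
#' @export
scar_config <- function(loh_min_len = 15e6,
                        tai_min_len = 11e6,
                        lst_min_seg = 10e6,
                        lst_smooth_len = 3e6,
                        telomere_tolerance = 0) {
  cfg <- list(loh_min_len = loh_min_len,
              tai_min_len = tai_min_len,
              lst_min_seg = lst_min_seg,
              lst_smooth_len = lst_smooth_len,
              telomere_tolerance = telomere_tolerance)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x >= 0, logical(1))))
  structure(cfg, class = "scar_config")
}

#' Genomic LOH score
#'
#' Counts loss-of-heterozygosity segments (`b_cn == 0` with at least one
#' retained copy, `total_cn >= 1`) longer than `min_len`, excluding any LOH
#' region that spans an entire chromosome. For the whole-chromosome
#' exclusion, abutting LOH segments are treated as one region: if the
#' region reaches both chromosome ends (within `telomere_tolerance`), none
#' of its segments are counted.
#'
#' @param profile a [segment_profile()].
#' @param arms an [arm_table()].
#' @param min_len minimum qualifying length in bp (exclusive bound).
#' @param telomere_tolerance bp slack for the whole-chromosome test.
#' @return non-negative integer count.
#' @export
compute_loh <- function(profile, arms, min_len = 15e6,
                        telomere_tolerance = 0) {
  stopifnot(inherits(profile, "segment_profile"))
  chr <- profile$chromosome
  start <- profile$start; end <- profile$end
  is_loh <- profile$b_cn == 0 & profile$total_cn >= 1
  clen <- stats::setNames(arms$chrom_length, arms$chromosome)
  total <- 0L
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    loh <- is_loh[i]
    if (!any(loh)) next
    s <- start[i]; e <- end[i]
    n <- length(i)
    # maximal runs of abutting LOH segments
    new_run <- loh & (c(TRUE, !loh[-n]) | c(TRUE, s[-1] != e[-n] + 1))
    run_id <- cumsum(new_run)
    run_id[!loh] <- 0L
    for (r in unique(run_id[run_id > 0L])) {
      m <- which(run_id == r)
      whole_chrom <- s[m[1]] <= 1 + telomere_tolerance &&
        e[m[length(m)]] >= clen[[ch]] - telomere_tolerance
      if (whole_chrom) next
      total <- total + sum(e[m] - s[m] + 1 > min_len)
    }
  }
  as.integer(total)
}

#' Telomeric allelic imbalance score
#'
#' Counts allelically imbalanced segments (`a_cn != b_cn`) of length at
#' least `min_len` that touch a chromosome end (start within
#' `telomere_tolerance` of base 1, or end within it of the chromosome
#' length) and do not cross the centromere, i.e. do not extend strictly
#' into both arms (`start < centromere_start` and `end > centromere_end`).
#'
#' @inheritParams compute_loh
#' @param min_len minimum qualifying length in bp (inclusive bound).
#' @return non-negative integer count.
#' @export
compute_tai <- function(profile, arms, min_len = 11e6,
                        telomere_tolerance = 0) {
  stopifnot(inherits(profile, "segment_profile"))
  i <- match(profile$chromosome, arms$chromosome)
  clen <- arms$chrom_length[i]
  cen_s <- arms$centromere_start[i]
  cen_e <- arms$centromere_end[i]
  touches <- profile$start <= 1 + telomere_tolerance |
    profile$end >= clen - telomere_tolerance
  crosses_cen <- profile$start < cen_s & profile$end > cen_e
  qual <- profile$a_cn != profile$b_cn &
    profile$end - profile$start + 1 >= min_len & touches & !crosses_cen
  as.integer(sum(qual))
}

# LST transitions on one arm, given that arm's clipped segment vectors
# sorted by start. State = (total_cn, b_cn).
lst_one_arm <- function(start, end, tot, b, min_seg, smooth_len) {
  keep <- end - start + 1 >= smooth_len
  start <- start[keep]; end <- end[keep]; tot <- tot[keep]; b <- b[keep]
  n <- length(start)
  if (n < 2) return(0L)
  # fuse same-state neighbours across gaps <= smooth_len
  k <- 1L
  for (i in 2:n) {
    gap <- start[i] - end[k] - 1
    if (tot[i] == tot[k] && b[i] == b[k] && gap <= smooth_len) {
      end[k] <- end[i]
    } else {
      k <- k + 1L
      start[k] <- start[i]; end[k] <- end[i]
      tot[k] <- tot[i]; b[k] <- b[i]
    }
  }
  if (k < 2) return(0L)
  start <- start[1:k]; end <- end[1:k]; tot <- tot[1:k]; b <- b[1:k]
  len <- end - start + 1
  i <- seq_len(k - 1L)
  gaps <- start[i + 1] - end[i] - 1
  diff_state <- tot[i + 1] != tot[i] | b[i + 1] != b[i]
  sum(diff_state & gaps <= smooth_len &
        len[i] >= min_seg & len[i + 1] >= min_seg)
}

#' Large-scale state transition score
#'
#' Per chromosome arm: segments are clipped to the arm, pieces shorter than
#' `smooth_len` are removed, remaining same-state neighbours (state =
#' the `(total_cn, b_cn)` pair) separated by at most `smooth_len` are
#' fused, and then every junction between two different-state segments that
#' are each at least `min_seg` long with an inter-segment gap of at most
#' `smooth_len` counts as one transition. The genome-wide sum is returned.
#'
#' @inheritParams compute_loh
#' @param min_seg minimum flanking-segment length in bp.
#' @param smooth_len smoothing scale in bp (short-segment removal, fusion
#'   gap, and maximum junction gap).
#' @return non-negative integer count.
#' @export
compute_lst <- function(profile, arms, min_seg = 10e6, smooth_len = 3e6) {
  stopifnot(inherits(profile, "segment_profile"))
  chr <- profile$chromosome
  total <- 0L
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    a <- which(arms$chromosome == ch)
    bounds <- list(c(1, arms$centromere_start[a] - 1),
                   c(arms$centromere_end[a] + 1, arms$chrom_length[a]))
    for (bd in bounds) {
      keep <- profile$end[i] >= bd[1] & profile$start[i] <= bd[2]
      j <- i[keep]
      if (length(j) == 0) next
      total <- total + lst_one_arm(
        pmax(profile$start[j], bd[1]), pmin(profile$end[j], bd[2]),
        profile$total_cn[j], profile$b_cn[j], min_seg, smooth_len
      )
    }
  }
  as.integer(total)
}

#' HRD score: TAI + LST + LOH
#'
#' Computes the three genomic scar components and their sum for one sample.
#'
#' @param profile a [segment_profile()].
#' @param arms an [arm_table()].
#' @param config a [scar_config()].
#' @return one-row `data.frame` with columns `sample_id`, `tai`, `lst`,
#'   `loh`, `hrd_score` (`hrd_score = tai + lst + loh`).
#' @examples
#' arms <- toy_genome()
#' prof <- segment_profile(data.frame(
#'   sample_id = "S1", chromosome = "chr1", start = 1, end = 100e6,
#'   total_cn = 2, a_cn = 1, b_cn = 1), arms)
#' compute_hrd_score(prof, arms)  # balanced diploid: all zero
#' @export
compute_hrd_score <- function(profile, arms, config = scar_config()) {
  stopifnot(inherits(config, "scar_config"))
  x <- scar_components(profile, arms, config)
  data.frame(sample_id = attr(profile, "sample_id"),
             tai = x[1], lst = x[2], loh = x[3],
             hrd_score = sum(x),
             stringsAsFactors = FALSE)
}

scar_components <- function(profile, arms, config) {
  c(compute_tai(profile, arms, min_len = config$tai_min_len,
                telomere_tolerance = config$telomere_tolerance),
    compute_lst(profile, arms, min_seg = config$lst_min_seg,
                smooth_len = config$lst_smooth_len),
    compute_loh(profile, arms, min_len = config$loh_min_len,
                telomere_tolerance = config$telomere_tolerance))
}

#' Score a cohort of segment profiles
#'
#' @param profiles list of [segment_profile()]s (e.g. from
#'   [read_segment_table()]).
#' @inheritParams compute_hrd_score
#' @return `data.frame` with one row per sample (`sample_id`, `tai`, `lst`,
#'   `loh`, `hrd_score`).
#' @export
score_cohort <- function(profiles, arms, config = scar_config()) {
  stopifnot(inherits(config, "scar_config"))
  comp <- vapply(profiles, scar_components, integer(3),
                 arms = arms, config = config)
  if (length(profiles) == 0) comp <- matrix(integer(0), 3, 0)
  data.frame(
    sample_id = vapply(profiles, attr, character(1), "sample_id"),
    tai = comp[1, ], lst = comp[2, ], loh = comp[3, ],
    hrd_score = as.integer(colSums(comp)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write per-sample scar scores to TSV
#'
#' @param scores data.frame from [score_cohort()].
#' @param path output path.
#' @export
write_scar_table <- function(scores, path) {
  out <- scores
  names(out) <- c("sample_id", "TAI", "LST", "LOH", "HRD_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
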