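#' Chromosome arm tables
#'
#' An arm table describes the chromosomes of a genome: total length and the
#' centromere interval splitting each chromosome into a p and a q arm. All
#' scar-score definitions ("telomeric", "not crossing the centromere",
#' "per arm") are evaluated against an arm table, so the same validation is
#' applied to the packaged toy genome and to any user-supplied table.
#'
#' Coordinates throughout the package are 1-based and inclusive.
#'
#' @param chromosome character vector of unique chromosome labels.
#' @param chrom_length integer vector of chromosome lengths in bp.
#' @param centromere_start,centromere_end centromere interval (bp), with
#'   `0 < centromere_start < centromere_end < chrom_length`.
#' @return A `data.frame` of class `arm_table` with one row per chromosome.
#' @examples
#' arm_table("chr1", 100e6, 45e6, 55e6)
#' @export
arm_table <- function(chromosome, chrom_length, centromere_start,
                      centromere_end) {
  at <- data.frame(
    chromosome = as.character(chromosome),
    chrom_length = as.numeric(chrom_length),
    centromere_start = as.numeric(centromere_start),
    centromere_end = as.numeric(centromere_end),
    stringsAsFactors = FALSE
  )
  validate_arm_table(at)
}

#' @rdname arm_table
#' @param arms a candidate arm table to validate.
#' @export
validate_arm_table <- function(arms) {
  req <- c("chromosome", "chrom_length", "centromere_start", "centromere_end")
  missing_cols <- setdiff(req, names(arms))
  if (length(missing_cols) > 0) {
    stop("arm table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(arms$chromosome)) {
    stop("arm table has duplicated chromosome labels")
  }
  bad <- !(arms$centromere_start > 0 &
             arms$centromere_start < arms$centromere_end &
             arms$centromere_end < arms$chrom_length)
  if (any(bad)) {
    stop("invalid centromere interval for chromosome(s): ",
         paste(arms$chromosome[bad], collapse = ", "),
         " (need 0 < centromere_start < centromere_end < chrom_length)")
  }
  class(arms) <- c("arm_table", "data.frame")
  arms
}

#' Packaged toy genome
#'
#' A deterministic small genome for tests and simulation: `n_chromosomes`
#' chromosomes of `chrom_length` bp each, centromere spanning 45-55% of the
#' chromosome. The default (3 x 100 Mb, centromere at 45-55 Mb) is the
#' fixture genome used throughout the test-suite; the synthetic cohort
#' generator uses a larger variant so that randomly drawn scar-event counts
#' always fit.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @return an [arm_table()].
#' @export
toy_genome <- function(n_chromosomes = 3, chrom_length = 100e6) {
  arm_table(
    chromosome = paste0("chr", seq_len(n_chromosomes)),
    chrom_length = rep(chrom_length, n_chromosomes),
    centromere_start = rep(0.45 * chrom_length, n_chromosomes),
    centromere_end = rep(0.55 * chrom_length, n_chromosomes)
  )
}

#' Read an arm table from a TSV file
#'
#' Expected columns: `chrom`, `length`, `cen_start`, `cen_end` (or the
#' canonical names used by [arm_table()]).
#'
#' @param path path to a tab-separated file with a header.
#' @return an [arm_table()].
#' @export
read_arm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  alias <- c(chrom = "chromosome", length = "chrom_length",
             cen_start = "centromere_start", cen_end = "centromere_end")
  for (a in names(alias)) {
    if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  validate_arm_table(df)
}

seg_columns <- c("sample_id", "chromosome", "start", "end",
                 "total_cn", "a_cn", "b_cn")

new_segment_profile <- function(segments, sample_id, ploidy = NULL) {
  rownames(segments) <- NULL
  if (is.null(ploidy)) {
    len <- segments$end - segments$start + 1
    ploidy <- if (nrow(segments) == 0) NA_real_ else {
      sum(len * segments$total_cn) / sum(len)
    }
  }
  structure(segments,
            sample_id = sample_id,
            ploidy = ploidy,
            class = c("segment_profile", "data.frame"))
}

#' Build a validated allele-specific segment profile
#'
#' A segment profile is one sample's set of allele-specific copy-number
#' segments: contiguous intervals with total, major (`a_cn`) and minor
#' (`b_cn`) copy number. Validation enforces `start <= end`,
#' `a_cn >= b_cn` (major/minor are swapped with a warning if supplied the
#' other way round), `a_cn + b_cn == total_cn`, non-overlap within a
#' chromosome, and that every chromosome exists in the arm table. Segments
#' are returned sorted by (chromosome, start).
#'
#' @param segments data.frame with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `total_cn`, `a_cn`, `b_cn` (1-based inclusive bp).
#' @param arms an [arm_table()].
#' @param ploidy optional sample mean copy number; computed as the
#'   length-weighted mean of `total_cn` when omitted.
#' @return a `segment_profile` (a data.frame with `sample_id` and `ploidy`
#'   attributes).
#' @export
segment_profile <- function(segments, arms, ploidy = NULL) {
  missing_cols <- setdiff(seg_columns, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  segments <- segments[, seg_columns]
  sid <- unique(segments$sample_id)
  if (length(sid) > 1) {
    stop("a segment profile must contain exactly one sample, got: ",
         paste(sid, collapse = ", "))
  }
  if (length(sid) == 0) sid <- NA_character_

  num_cols <- c("start", "end", "total_cn", "a_cn", "b_cn")
  for (cn in num_cols) segments[[cn]] <- as.numeric(segments[[cn]])
  if (anyNA(segments[num_cols])) {
    bad <- which(rowSums(is.na(segments[num_cols])) > 0)
    stop("malformed (non-numeric or missing) value in segment row(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(segments$start > segments$end)) {
    stop("segment with start > end for sample ", sid)
  }
  swap <- segments$a_cn < segments$b_cn
  if (any(swap)) {
    warning(sum(swap), " segment(s) had a_cn < b_cn; ",
            "major/minor alleles swapped")
    tmp <- segments$a_cn[swap]
    segments$a_cn[swap] <- segments$b_cn[swap]
    segments$b_cn[swap] <- tmp
  }
  if (any(segments$a_cn + segments$b_cn != segments$total_cn)) {
    stop("a_cn + b_cn != total_cn in sample ", sid)
  }
  if (any(segments$total_cn < 0 | segments$b_cn < 0)) {
    stop("negative copy number in sample ", sid)
  }
  unknown <- setdiff(unique(segments$chromosome), arms$chromosome)
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from the arm table: ",
         paste(unknown, collapse = ", "))
  }
  segments <- segments[order(segments$chromosome, segments$start), ]
  for (chr in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chr, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments for sample ", sid, " on ", chr)
    }
    clen <- arms$chrom_length[arms$chromosome == chr]
    if (any(s$end > clen)) {
      stop("segment beyond chromosome end on ", chr, " for sample ", sid)
    }
  }
  new_segment_profile(segments, sid, ploidy)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> sample %s: %d segments, ploidy %.3g\n",
              attr(x, "sample_id"), nrow(x), attr(x, "ploidy")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read allele-specific segment tables
#'
#' Reads a scarHRD-style tab-separated segment table (columns `SampleID`,
#' `Chromosome`, `Start_position`, `End_position`, `total_cn`, `A_cn`,
#' `B_cn`; the canonical lower-case names are also accepted) and returns one
#' validated, sorted [segment_profile()] per sample. Coordinates are 1-based
#' inclusive.
#'
#' @param path path to the TSV file.
#' @param arms an [arm_table()] all chromosomes must belong to.
#' @return named list of `segment_profile`s, one per sample.
#' @export
read_segment_table <- function(path, arms) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  alias <- c(SampleID = "sample_id", Chromosome = "chromosome",
             Start_position = "start", End_position = "end",
             A_cn = "a_cn", B_cn = "b_cn")
  for (a in names(alias)) {
    if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  missing_cols <- setdiff(seg_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("segment table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- c("start", "end", "total_cn", "a_cn", "b_cn")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad) > 0) {
      stop("parse error in ", path, ", line ", bad[1] + 1,
           ": non-numeric value '", df[[cn]][bad[1]], "' in column ", cn)
    }
    df[[cn]] <- v
  }
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  profiles <- lapply(split(df, df$sample_id), segment_profile, arms = arms)
  profiles[unique(df$sample_id)]
}

#' Write segment profiles to a TSV file
#'
#' Inverse of [read_segment_table()]; writes the scarHRD-style header.
#'
#' @param profiles a `segment_profile` or list of them.
#' @param path output file path.
#' @export
write_segment_table <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  df <- rbind_all(lapply(profiles, as.data.frame))
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 7),
                                        seg_columns))
  }
  out_names <- c("SampleID", "Chromosome", "Start_position", "End_position",
                 "total_cn", "A_cn", "B_cn")
  names(df) <- out_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fuse equal-state adjacent segments
#'
#' Adjacent segments of a profile with identical `(total_cn, a_cn, b_cn)`
#' state and an inter-segment gap of at most `tolerance_bp` are fused into a
#' single segment. Segments differing in any copy number, or separated by a
#' larger gap, are left untouched. The operation is idempotent and never
#' increases the number of covered bases.
#'
#' @param profile a [segment_profile()].
#' @param tolerance_bp maximum gap (bp) bridged by a fusion; `0` fuses only
#'   abutting segments.
#' @return a [segment_profile()].
#' @export
merge_adjacent <- function(profile, tolerance_bp = 0) {
  stopifnot(inherits(profile, "segment_profile"))
  if (nrow(profile) < 2) return(profile)
  seg <- as.data.frame(profile)
  keep <- list()
  for (chr in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == chr, ]
    cur <- s[1, ]
    rows <- list()
    for (i in seq_len(nrow(s))[-1]) {
      nxt <- s[i, ]
      same_state <- cur$total_cn == nxt$total_cn &&
        cur$a_cn == nxt$a_cn && cur$b_cn == nxt$b_cn
      gap <- nxt$start - cur$end - 1
      if (same_state && gap <= tolerance_bp) {
        cur$end <- nxt$end
      } else {
        rows[[length(rows) + 1]] <- cur
        cur <- nxt
      }
    }
    rows[[length(rows) + 1]] <- cur
    keep[[chr]] <- do.call(rbind, rows)
  }
  out <- rbind_all(keep)
  out <- out[order(out$chromosome, out$start), ]
  new_segment_profile(out, attr(profile, "sample_id"))
}

#' Sample mean copy number of a profile
#'
#' @param profile a [segment_profile()].
#' @return the length-weighted mean total copy number.
#' @export
profile_ploidy <- function(profile) attr(profile, "ploidy")
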