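#' SBS96 channel labels
#'
#' The 96 single-base-substitution channels in the conventional fixed
#' order: substitution class major (C>A, C>G, C>T, T>A, T>C, T>G), flanking
#' bases minor (5' base cycling slowest, then 3' base, each in A, C, G, T
#' order). Labels look like `"A[C>T]G"`. All spectra in the package are
#' pyrimidine-centred: substitutions observed with a purine reference are
#' reverse-complemented into this convention.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

comp_base <- function(x) unname(REVCOMP[x])

# Vectorised reverse-complement of 3-mers.
revcomp3 <- function(ctx) {
  paste0(comp_base(substr(ctx, 3, 3)), comp_base(substr(ctx, 2, 2)),
         comp_base(substr(ctx, 1, 1)))
}

# Map SNVs (ref, alt, trinucleotide context on the reported strand) to
# their pyrimidine-centred channel labels; vectorised.
snv_channel <- function(ref, alt, context) {
  bad <- substr(context, 2, 2) != ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop("context middle base '", substr(context[i], 2, 2),
         "' does not match ref '", ref[i], "'")
  }
  pur <- ref %in% c("A", "G")
  context[pur] <- revcomp3(context[pur])
  ref[pur] <- comp_base(ref[pur])
  alt[pur] <- comp_base(alt[pur])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' Read an SNV catalog from a MAF-like TSV
#'
#' Accepts either the canonical column names (`sample_id`, `chromosome`,
#' `position`, `ref`, `alt`, optional `context`) or common MAF aliases
#' (`Tumor_Sample_Barcode`, `Chromosome`, `Start_position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`). Rows whose ref or alt is not a
#' single A/C/G/T base (indels, MNVs) are dropped with a message stating
#' how many were skipped.
#'
#' @param path TSV path.
#' @return data.frame of SNV records.
#' @export
read_snv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  alias <- c(Tumor_Sample_Barcode = "sample_id", Chromosome = "chromosome",
             Start_position = "position", Reference_Allele = "ref",
             Tumor_Seq_Allele2 = "alt")
  for (a in names(alias)) {
    if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  req <- c("sample_id", "chromosome", "position", "ref", "alt")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("SNV table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  is_snv <- df$ref %in% names(REVCOMP) & df$alt %in% names(REVCOMP) &
    df$ref != df$alt
  if (any(!is_snv)) {
    message("skipped ", sum(!is_snv), " non-SNV record(s)")
    df <- df[is_snv, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

resolve_context_fasta <- function(snvs, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to resolve contexts from a FASTA file")
  }
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  vapply(seq_len(nrow(snvs)), function(i) {
    chr <- as.character(snvs$chromosome[i])
    pos <- snvs$position[i]
    if (!chr %in% names(genome)) {
      stop("cannot resolve context: chromosome ", chr, " not in FASTA")
    }
    if (pos < 2 || pos > Biostrings::width(genome[chr]) - 1) {
      stop("cannot resolve context at ", chr, ":", pos,
           " (too close to a sequence end)")
    }
    as.character(Biostrings::subseq(genome[[chr]], pos - 1, pos + 1))
  }, character(1))
}

#' Build an SBS96 spectrum from an SNV catalog
#'
#' Counts one sample's single-base substitutions into the 96
#' pyrimidine-centred channels of [sbs96_channels()]. Each SNV needs a
#' trinucleotide context, either inline (a `context` column, middle base
#' equal to `ref` on the reported strand) or resolved from `fasta`.
#' Purine-reference records are reverse-complemented; counts are conserved,
#' so `sum(spectrum) == nrow(snvs)`.
#'
#' @param snvs data.frame with columns `sample_id`, `chromosome`,
#'   `position`, `ref`, `alt` and optionally `context`; one sample only.
#' @param fasta optional path to a FASTA file used to resolve missing
#'   contexts.
#' @return named integer vector of length 96 (class `sbs96_spectrum`, with
#'   a `sample_id` attribute).
#' @examples
#' snv <- data.frame(sample_id = "S1", chromosome = "chr1", position = 100,
#'                   ref = "C", alt = "T", context = "ACG")
#' spec <- build_spectrum(snv)
#' spec[spec > 0]  # one count in A[C>T]G
#' @export
build_spectrum <- function(snvs, fasta = NULL) {
  sid <- unique(snvs$sample_id)
  if (length(sid) > 1) {
    stop("build_spectrum expects one sample, got: ",
         paste(sid, collapse = ", "))
  }
  if (length(sid) == 0) sid <- NA_character_
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  if (nrow(snvs) > 0) {
    ok_base <- snvs$ref %in% names(REVCOMP) & snvs$alt %in% names(REVCOMP) &
      snvs$ref != snvs$alt
    if (any(!ok_base)) {
      stop("non-SNV record at row ", which(!ok_base)[1],
           " (use read_snv_table() to drop indels/MNVs first)")
    }
    ctx <- if ("context" %in% names(snvs)) as.character(snvs$context) else
      rep(NA_character_, nrow(snvs))
    need <- is.na(ctx) | !nzchar(ctx)
    if (any(need)) {
      if (is.null(fasta)) {
        stop("record ", which(need)[1], " (", snvs$chromosome[which(need)[1]],
             ":", snvs$position[which(need)[1]],
             ") has no context and no FASTA was supplied")
      }
      ctx[need] <- resolve_context_fasta(snvs[need, , drop = FALSE], fasta)
    }
    bad_ctx <- nchar(ctx) != 3 | substr(ctx, 2, 2) != snvs$ref
    if (any(bad_ctx)) {
      i <- which(bad_ctx)[1]
      stop("record ", i, " (", snvs$chromosome[i], ":", snvs$position[i],
           "): context '", ctx[i], "' does not match ref '", snvs$ref[i], "'")
    }
    ch <- snv_channel(as.character(snvs$ref), as.character(snvs$alt), ctx)
    tab <- table(factor(ch, levels = channels))
    counts <- stats::setNames(as.integer(tab), channels)
  }
  structure(counts, sample_id = sid, class = "sbs96_spectrum")
}

#' Build spectra for every sample in a catalog
#'
#' @inheritParams build_spectrum
#' @param snvs data.frame of SNV records for one or more samples.
#' @return named list of `sbs96_spectrum` vectors.
#' @export
build_spectra <- function(snvs, fasta = NULL) {
  sids <- unique(snvs$sample_id)
  chunks <- split(snvs, factor(snvs$sample_id, levels = sids))
  stats::setNames(lapply(chunks, build_spectrum, fasta = fasta), sids)
}

#' Read a reference signature matrix
#'
#' Reads a tab-separated signature matrix with a channel column and one
#' column per signature (probabilities over the 96 channels). Both the
#' packaged synthetic set and the COSMIC v2
#' `signatures_probabilities.txt` layout (with `Substitution Type`,
#' `Trinucleotide` and `Somatic Mutation Type` columns) are accepted; rows
#' are reordered to [sbs96_channels()] order.
#'
#' @param path TSV path; defaults to the packaged synthetic v2-like set
#'   (see [synthetic_signature_set()] for how it is constructed).
#' @return matrix (96 x n_signatures) with channel rownames; each column
#'   sums to 1 within 1e-6.
#' @export
read_signature_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_v2_like_signatures.tsv",
                        package = "hrdscreen", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if ("Somatic Mutation Type" %in% names(df)) {
    channel <- df[["Somatic Mutation Type"]]
    drop <- c("Substitution Type", "Trinucleotide", "Somatic Mutation Type")
    df <- df[, setdiff(names(df), drop), drop = FALSE]
  } else if ("channel" %in% names(df)) {
    channel <- df$channel
    df <- df[, setdiff(names(df), "channel"), drop = FALSE]
  } else {
    stop("signature matrix needs a 'channel' or 'Somatic Mutation Type' column")
  }
  num <- vapply(df, is.numeric, logical(1))
  mat <- as.matrix(df[, num, drop = FALSE])
  rownames(mat) <- channel
  validate_signature_matrix(mat)
}

#' @rdname read_signature_matrix
#' @param mat a candidate 96 x k probability matrix with channel rownames.
#' @export
validate_signature_matrix <- function(mat) {
  channels <- sbs96_channels()
  missing_ch <- setdiff(channels, rownames(mat))
  if (length(missing_ch) > 0) {
    stop("signature matrix is missing channel(s): ",
         paste(utils::head(missing_ch, 3), collapse = ", "),
         if (length(missing_ch) > 3) " ..." else "")
  }
  mat <- mat[channels, , drop = FALSE]
  if (any(mat < 0)) stop("signature profiles must be non-negative")
  sums <- colSums(mat)
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop("signature profile(s) do not sum to 1: ",
         paste(colnames(mat)[off], collapse = ", "))
  }
  mat
}

#' Cosine similarity of a spectrum to a named reference signature
#'
#' Computes `dot(u, v) / (|u| |v|)` between a raw SBS96 count spectrum and
#' one column of a reference signature matrix. Both vectors are
#' non-negative, so the value lies in `[0, 1]`; it is invariant to scaling
#' the counts. The optional `weights` hook multiplies both vectors
#' channel-wise before comparison (e.g. for exome-coverage normalisation).
#'
#' @param spectrum an `sbs96_spectrum` (or any named 96-vector of counts).
#' @param signatures matrix from [read_signature_matrix()].
#' @param name signature column to compare against.
#' @param weights optional positive 96-vector of per-channel weights.
#' @return cosine similarity in `[0, 1]`.
#' @export
cosine_to_signature <- function(spectrum, signatures = read_signature_matrix(),
                                name = "Signature 3", weights = NULL) {
  if (!name %in% colnames(signatures)) {
    stop("unknown signature '", name, "'; available: ",
         paste(colnames(signatures), collapse = ", "))
  }
  channels <- sbs96_channels()
  u <- as.numeric(spectrum[channels])
  if (anyNA(u)) stop("spectrum does not cover all 96 channels")
  if (sum(u) == 0) {
    stop("cosine similarity is undefined for an all-zero spectrum")
  }
  v <- signatures[channels, name]
  if (!is.null(weights)) {
    stopifnot(length(weights) == 96, all(weights > 0))
    u <- u * weights
    v <- v * weights
  }
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Per-sample signature-similarity table
#'
#' @param spectra named list from [build_spectra()].
#' @inheritParams cosine_to_signature
#' @return data.frame with `sample_id`, `n_snvs`, `signature3_cosine`
#'   (`NA` for all-zero spectra, which cannot be compared).
#' @export
signature_cosine_table <- function(spectra,
                                   signatures = read_signature_matrix(),
                                   name = "Signature 3") {
  rows <- lapply(spectra, function(sp) {
    n <- sum(sp)
    val <- if (n == 0) NA_real_ else
      cosine_to_signature(sp, signatures, name)
    data.frame(sample_id = attr(sp, "sample_id"), n_snvs = n,
               signature3_cosine = val, stringsAsFactors = FALSE)
  })
  rbind_all(rows) %||% data.frame(sample_id = character(0),
                                  n_snvs = integer(0),
                                  signature3_cosine = numeric(0))
}

#' Synthetic v2-like reference signature set
#'
#' The package cannot redistribute the COSMIC v2 signature matrix, so it
#' ships a synthetic stand-in with the qualitative structure relevant to
#' this pipeline, built deterministically by this function (the packaged
#' `extdata/synthetic_v2_like_signatures.tsv` is its output):
#'
#' * `Signature 1`: clock-like CpG deamination caricature - 60% of its mass
#'   evenly on the four `N[C>T]G` channels, the rest uniform.
#' * `Signature 3`: flat ("featureless") profile over all channels except
#'   the four `N[C>T]G` channels, where it has mass 0. The zero channels
#'   make it distinguishable from `Signature 1` and give an exact
#'   orthogonality case.
#' * `Signature 5`: uniform over all 96 channels.
#'
#' Real analyses should pass the genuine COSMIC v2 matrix to
#' [read_signature_matrix()].
#'
#' @return 96 x 3 probability matrix with channel rownames.
#' @export
synthetic_signature_set <- function() {
  channels <- sbs96_channels()
  ncg <- grepl("\\[C>T\\]G$", channels)
  sig1 <- ifelse(ncg, 0.6 / 4, 0.4 / 92)
  sig3 <- ifelse(ncg, 0, 1 / 92)
  sig5 <- rep(1 / 96, 96)
  mat <- cbind(`Signature 1` = sig1, `Signature 3` = sig3,
               `Signature 5` = sig5)
  rownames(mat) <- channels
  validate_signature_matrix(mat)
}

#' Write per-sample signature similarities to TSV
#'
#' @param tab data.frame from [signature_cosine_table()].
#' @param path output path.
#' @export
write_signature_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
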