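# Independent brute-force oracles: literal, loop-based transcriptions of
# the counting rules, deliberately written in a different style from the
# package implementations so that agreement is evidence, not tautology.

oracle_tai <- function(profile, arms, min_len = 11e6, tol = 0) {
  count <- 0
  for (i in seq_len(nrow(profile))) {
    seg <- profile[i, ]
    a <- arms[arms$chromosome == seg$chromosome, ]
    len <- seg$end - seg$start + 1
    imbalanced <- seg$a_cn != seg$b_cn
    touches_telomere <- (seg$start <= 1 + tol) ||
      (seg$end >= a$chrom_length - tol)
    crosses_centromere <- (seg$start < a$centromere_start) &&
      (seg$end > a$centromere_end)
    if (imbalanced && len >= min_len && touches_telomere &&
        !crosses_centromere) {
      count <- count + 1
    }
  }
  count
}

oracle_loh <- function(profile, arms, min_len = 15e6, tol = 0) {
  count <- 0
  for (chr in unique(profile$chromosome)) {
    s <- profile[profile$chromosome == chr, ]
    s <- s[order(s$start), ]
    clen <- arms$chrom_length[arms$chromosome == chr]
    is_loh <- s$b_cn == 0 & s$total_cn >= 1
    # collect maximal abutting LOH runs, one explicit scan
    runs <- list()
    current <- NULL
    for (i in seq_len(nrow(s))) {
      if (!is_loh[i]) { if (!is.null(current)) runs <- c(runs, list(current));
        current <- NULL; next }
      if (is.null(current)) {
        current <- i
      } else if (s$start[i] == s$end[current[length(current)]] + 1) {
        current <- c(current, i)
      } else {
        runs <- c(runs, list(current)); current <- i
      }
    }
    if (!is.null(current)) runs <- c(runs, list(current))
    for (run in runs) {
      spans_whole <- s$start[run[1]] <= 1 + tol &&
        s$end[run[length(run)]] >= clen - tol
      if (spans_whole) next
      for (i in run) {
        if (s$end[i] - s$start[i] + 1 > min_len) count <- count + 1
      }
    }
  }
  count
}

oracle_lst <- function(profile, arms, min_seg = 10e6, smooth = 3e6) {
  count <- 0
  for (chr in unique(profile$chromosome)) {
    a <- arms[arms$chromosome == chr, ]
    for (arm in list(c(1, a$centromere_start - 1),
                     c(a$centromere_end + 1, a$chrom_length))) {
      s <- profile[profile$chromosome == chr, ]
      s <- s[order(s$start), ]
      # clip to the arm, one row at a time
      pieces <- list()
      for (i in seq_len(nrow(s))) {
        lo <- max(s$start[i], arm[1]); hi <- min(s$end[i], arm[2])
        if (lo > hi) next
        pieces <- c(pieces, list(list(start = lo, end = hi,
                                      tot = s$total_cn[i], b = s$b_cn[i])))
      }
      # drop short pieces
      pieces <- Filter(function(p) p$end - p$start + 1 >= smooth, pieces)
      # fuse same-state neighbours (gap <= smooth) until stable
      repeat {
        fused_any <- FALSE
        if (length(pieces) >= 2) {
          for (i in seq_len(length(pieces) - 1)) {
            p1 <- pieces[[i]]; p2 <- pieces[[i + 1]]
            if (p1$tot == p2$tot && p1$b == p2$b &&
                p2$start - p1$end - 1 <= smooth) {
              pieces[[i]]$end <- p2$end
              pieces[[i + 1]] <- NULL
              fused_any <- TRUE
              break
            }
          }
        }
        if (!fused_any) break
      }
      # count qualifying junctions
      if (length(pieces) >= 2) {
        for (i in seq_len(length(pieces) - 1)) {
          p1 <- pieces[[i]]; p2 <- pieces[[i + 1]]
          state_change <- p1$tot != p2$tot || p1$b != p2$b
          long_enough <- (p1$end - p1$start + 1 >= min_seg) &&
            (p2$end - p2$start + 1 >= min_seg)
          close_enough <- p2$start - p1$end - 1 <= smooth
          if (state_change && long_enough && close_enough) count <- count + 1
        }
      }
    }
  }
  count
}

# Holm step-down, straight from the definition.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# tie-free values into groups of the observed sizes.
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  splits <- utils::combn(n, length(a))
  u_obs <- sum(rank(pooled)[seq_along(a)]) -
    length(a) * (length(a) + 1) / 2
  u_all <- apply(splits, 2, function(idx) {
    sum(rank(pooled)[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}
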