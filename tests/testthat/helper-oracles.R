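# Independent brute-force oracles used to validate the interval, scanning
# and ORF machinery. These deliberately avoid the package's code paths:
# interval questions are answered on per-base logical masks, ORFs by a
# position-by-position walk, binomial tails by direct pmf enumeration.

mask_of <- function(df, chromlens) {
  masks <- lapply(chromlens, function(len) logical(len))
  for (i in seq_len(NROW(df))) {
    s <- df$start[i]
    e <- df$end[i]
    if (e > s) {
      m <- masks[[df$chrom[i]]]
      m[(s + 1):e] <- TRUE
      masks[[df$chrom[i]]] <- m
    }
  }
  masks
}

oracle_union_len <- function(df, chromlens) {
  sum(vapply(mask_of(df, chromlens), sum, 0))
}

oracle_intersect_len <- function(a, b, chromlens) {
  ma <- mask_of(a, chromlens)
  mb <- mask_of(b, chromlens)
  sum(vapply(names(chromlens), function(ch) sum(ma[[ch]] & mb[[ch]]), 0))
}

oracle_cov_frac <- function(df, window, chromlens) {
  m <- mask_of(df, chromlens)[[window$chrom]]
  mean(m[(window$start + 1):window$end])
}

rand_intervals <- function(n, chromlens, max_len = 500) {
  chrom <- sample(names(chromlens), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (unlist(chromlens)[chrom] - len))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# ORF oracle: walk every position, then collapse nested ORFs sharing a
# terminator to the longest (earliest start).
oracle_orfs <- function(seq, min_aa) {
  s <- toupper(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  recs <- list()
  if (n >= 3) {
    for (p0 in 0:(n - 3)) {
      if (substr(s, p0 + 1, p0 + 3) != "ATG") next
      q <- p0
      len <- 0L
      term <- "end"
      while (TRUE) {
        if (q + 3 > n) {
          term <- "end"
          break
        }
        cd <- substr(s, q + 1, q + 3)
        if (cd %in% stops) {
          term <- "stop"
          break
        }
        if (grepl("N", cd, fixed = TRUE)) {
          term <- "ambiguous"
          break
        }
        len <- len + 1L
        q <- q + 3
      }
      if (len >= min_aa) {
        recs[[length(recs) + 1L]] <- data.frame(
          start = p0, end = p0 + 3 * len + if (term == "stop") 3L else 0L,
          frame = p0 %% 3, length_aa = len, terminator = term,
          open_ended = term == "end", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(start = numeric(), end = numeric(), frame = integer(),
                      length_aa = integer(), terminator = character(),
                      open_ended = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  # terminator anchor: first base after the coding run, per frame
  key <- paste(out$frame, out$start + 3 * out$length_aa, out$terminator)
  keep <- unlist(lapply(split(seq_len(NROW(out)), key), function(idx) {
    idx[which.max(out$length_aa[idx])]
  }), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_binom_tail <- function(k, n, p) {
  i <- 0:n
  pmf <- choose(n, i) * p^i * (1 - p)^(n - i)
  sum(pmf[i >= k])
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small synthetic repeat table from raw intervals
as_repeats <- function(df, rep_class = "LINE", rep_family = "L1",
                       rep_name = "L1Md_T") {
  if (NROW(df) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      rep_name = character(), rep_class = character(),
                      rep_family = character(), lineage = character(),
                      divergence = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = df$chrom, start = df$start, end = df$end, strand = "+",
             rep_name = rep_name, rep_class = rep_class,
             rep_family = rep_family, lineage = NA_character_,
             divergence = NA_real_, stringsAsFactors = FALSE)
}
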