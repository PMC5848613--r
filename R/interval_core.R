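# Interval-set arithmetic. All coordinates in this package are 0-based
# half-open (BED convention); IRanges (1-based closed) is used internally and
# converted at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_gr <- function(df, seqlevels = NULL) {
  chrom <- as.character(df$chrom)
  if (is.null(seqlevels)) seqlevels <- sort(unique(chrom), method = "radix")
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = as.numeric(df$start) + 1,
                              end = as.numeric(df$end))
  )
}

.check_intervals <- function(df, what = "interval") {
  if (NROW(df) == 0L) return(invisible(df))
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop(what, "s need chrom/start/end columns")
  }
  bad <- which(df$end < df$start | df$start < 0)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s", what, bad[1],
                 df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

.sort_features <- function(df) {
  o <- order(as.character(df$chrom), df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Union of genomic intervals
#'
#' Collapses a collection of (possibly overlapping) intervals into a sorted,
#' disjoint interval set in which every covered base is counted once.
#' Book-ended intervals are merged (coverage is a base-set property under
#' half-open semantics); zero-length intervals cover no bases and are dropped.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return a data frame of class `interval_set`: per chromosome sorted,
#'   disjoint, non-adjacent intervals. Chromosomes are ordered by name
#'   (C-locale), so the result is independent of input order.
#' @details Implemented as a vectorized O(n log n) sort-and-scan (sort by
#'   chromosome and start, break a run where the next start exceeds the
#'   running maximum end); the per-base brute-force oracle and an
#'   independent IRanges route verify it in the test suite.
#' @export
union_intervals <- function(intervals) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (NROW(intervals) == 0L) {
    return(structure(empty, class = c("interval_set", "data.frame")))
  }
  .check_intervals(intervals)
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
  if (NROW(intervals) == 0L) {
    return(structure(empty, class = c("interval_set", "data.frame")))
  }
  ch <- as.character(intervals$chrom)
  s <- as.numeric(intervals$start)
  e <- as.numeric(intervals$end)
  o <- order(ch, s, e, method = "radix")
  ch <- ch[o]; s <- s[o]; e <- e[o]
  n <- length(s)
  new_chrom <- c(TRUE, ch[-1L] != ch[-n])
  hi <- stats::ave(e, cumsum(new_chrom), FUN = cummax)  # running max end
  brk <- new_chrom | c(TRUE, s[-1L] > hi[-n])           # book-ends merge
  grp <- cumsum(brk)
  out <- data.frame(chrom = ch[brk], start = s[brk],
                    end = as.numeric(tapply(e, grp, max)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("interval_set", "data.frame"))
}

# Covered bases strictly below x, for one chromosome's sorted disjoint
# interval set (vectorized in x).
.covered_upto <- function(s, e, x) {
  if (length(s) == 0L) return(numeric(length(x)))
  cum0 <- c(0, cumsum(e - s))   # cum0[i] = bases covered by intervals < i
  idx <- findInterval(x, s)     # last interval whose start is <= x
  out <- numeric(length(x))
  pos <- idx > 0L
  out[pos] <- cum0[idx[pos]] + pmax(0, pmin(x[pos], e[idx[pos]]) -
                                      s[idx[pos]])
  out
}

.as_iset <- function(x) {
  if (inherits(x, "interval_set")) x else union_intervals(x)
}

#' Total length of an interval collection
#'
#' @param x data frame with `start`/`end` columns (0-based half-open).
#' @return total number of covered bases (after union if `x` is not already
#'   an `interval_set`).
#' @export
total_length <- function(x) {
  x <- .as_iset(x)
  sum(as.numeric(x$end) - as.numeric(x$start))
}

#' Number of bases covered by both of two interval collections
#'
#' Symmetric; each base is counted at most once.
#'
#' @param a,b interval collections (data frames with chrom/start/end).
#' @return intersection length in bp.
#' @export
intersect_length <- function(a, b) {
  a <- .as_iset(a)
  b <- .as_iset(b)
  if (NROW(a) == 0L || NROW(b) == 0L) return(0)
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    A <- a[a$chrom == ch, , drop = FALSE]
    B <- b[b$chrom == ch, , drop = FALSE]
    total <- total + sum(.covered_upto(A$start, A$end, B$end) -
                           .covered_upto(A$start, A$end, B$start))
  }
  total
}

#' Fraction of a window covered by an interval set
#'
#' @param features interval collection (e.g. the union of LINE annotations).
#' @param window a single interval: data frame row or list with `chrom`,
#'   `start`, `end`.
#' @return covered fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(features, window) {
  w <- data.frame(chrom = as.character(window$chrom[[1]]),
                  start = as.numeric(window$start[[1]]),
                  end = as.numeric(window$end[[1]]),
                  stringsAsFactors = FALSE)
  width <- w$end - w$start
  if (width <= 0) stop("zero-length window")
  intersect_length(features, w) / width
}

#' Seeded random placement of fixed-length regions on a genome
#'
#' Mimics the shuffle idiom of genome-arithmetic tools: for each draw the
#' chromosome is chosen with probability proportional to the number of valid
#' start positions, `max(0, chrom_len - length + 1)`, and the start is uniform
#' on `[0, chrom_len - length]`. Draws are independent and may overlap each
#' other (and any real feature) unless an exclusion set is supplied.
#'
#' @param genome a [genome_map()].
#' @param lengths region lengths in bp; draw `i` uses
#'   `lengths[((i - 1) %% length(lengths)) + 1]` (cycled).
#' @param n_total number of regions to draw.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param exclude optional interval collection; draws overlapping it are
#'   rejected and redrawn (off by default).
#' @param max_tries rejection limit per draw when `exclude` is used.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
sample_random_regions <- function(genome, lengths, n_total, seed,
                                  exclude = NULL, max_tries = 1000L) {
  stopifnot(inherits(genome, "genome_map"), n_total >= 0)
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || any(lengths < 1)) {
    stop("region lengths must be positive")
  }
  glen <- as.numeric(genome)
  for (L in unique(lengths)) {
    if (all(glen - L + 1 <= 0)) {
      stop(sprintf("length %s exceeds every chromosome",
                   format(L, scientific = FALSE)))
    }
  }
  if (!is.null(exclude)) exclude <- .as_iset(exclude)
  k <- length(lengths)
  nm <- names(genome)
  withr::with_seed(as.integer(seed), {
    chrom <- character(n_total)
    start <- numeric(n_total)
    for (i in seq_len(n_total)) {
      L <- lengths[((i - 1L) %% k) + 1L]
      w <- pmax(0, glen - L + 1)
      for (try in seq_len(max_tries)) {
        ci <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
        st <- floor(stats::runif(1) * w[ci])
        if (is.null(exclude)) break
        ex <- exclude[exclude$chrom == nm[ci] &
                        exclude$start < st + L & exclude$end > st, ,
                      drop = FALSE]
        if (NROW(ex) == 0L) break
        if (try == max_tries) {
          stop("could not place region outside the exclusion set after ",
               max_tries, " tries")
        }
      }
      chrom[i] <- nm[ci]
      start[i] <- st
      end_i <- st + L
      stopifnot(end_i <= glen[ci])
    }
    lens <- lengths[((seq_len(n_total) - 1L) %% k) + 1L]
    data.frame(chrom = chrom, start = start, end = start + lens,
               stringsAsFactors = FALSE)
  })
}
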