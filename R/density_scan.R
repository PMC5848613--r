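# Sliding-window repeat-coverage scanning and dense-array calling.

#' Scan parameters for the window scan and array caller
#'
#' The `line_array` preset is the genome-wide screen (100-kb windows, 10-kb
#' steps, coverage strictly > 0.70, regions of at least 100 kb); the
#' `imprinted` preset is the finer variant used to screen imprinted domains
#' (50-kb windows, 10-kb steps, coverage > 0.40, regions of at least 50 kb).
#' Explicit arguments override the preset.
#'
#' @param preset `"line_array"` or `"imprinted"`.
#' @param window window width W in bp.
#' @param step step s in bp; `0 < step <= window`.
#' @param min_density window qualification threshold d (strict `>`).
#' @param min_length minimum region span L in bp; `min_length >= window`.
#' @param class_filter predicate: takes the repeat data frame, returns a
#'   logical vector selecting the features whose coverage is scanned.
#'   Defaults to `rep_class == "LINE"`. See [l1_filter()] for an L1-only
#'   predicate.
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(preset = c("line_array", "imprinted"),
                        window = NULL, step = NULL, min_density = NULL,
                        min_length = NULL, class_filter = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    line_array = list(window = 100000, step = 10000,
                      min_density = 0.70, min_length = 100000),
    imprinted = list(window = 50000, step = 10000,
                     min_density = 0.40, min_length = 50000))
  p <- list(
    preset = preset,
    window = window %||% def$window,
    step = step %||% def$step,
    min_density = min_density %||% def$min_density,
    min_length = min_length %||% def$min_length,
    class_filter = class_filter %||% line_filter()
  )
  stopifnot(p$step > 0, p$step <= p$window,
            p$min_density > 0, p$min_density <= 1,
            p$min_length >= p$window)
  structure(p, class = "scan_params")
}

#' Feature-class predicates
#'
#' `line_filter()` selects all LINE-class repeats (the genome-wide scan is a
#' LINE scan, not an L1-only scan); `l1_filter()` selects repeats whose
#' family starts with `"L1"`, as used for lineage stratification.
#'
#' @return a predicate function for [scan_params()].
#' @export
line_filter <- function() {
  function(repeats) repeats$rep_class == "LINE"
}

#' @rdname line_filter
#' @export
l1_filter <- function() {
  function(repeats) startsWith(repeats$rep_family, "L1")
}

#' Sliding-window repeat coverage scan
#'
#' Per chromosome, windows start at 0, s, 2s, ...; only windows fully inside
#' the chromosome (`start + W <= length`) are emitted so every fraction
#' shares the denominator W (partial end windows would inflate variance).
#' A chromosome shorter than W yields no windows. The covered fraction is
#' computed on the union of the class-filtered features, so each base counts
#' once regardless of overlapping annotations. The scan is strand-blind.
#'
#' @param repeats repeat data frame (see [read_repeats()]), validated against
#'   `genome`.
#' @param genome a [genome_map()].
#' @param params a [scan_params()].
#' @return data frame with `chrom`, `start`, `end`, `covered_bp`, `fraction`,
#'   sorted by (chrom, start).
#' @export
window_scan <- function(repeats, genome, params = scan_params()) {
  stopifnot(inherits(genome, "genome_map"), inherits(params, "scan_params"))
  .validate_against_genome(repeats, genome)
  keep <- params$class_filter(repeats)
  uni <- union_intervals(repeats[keep, c("chrom", "start", "end"),
                                 drop = FALSE])
  W <- params$window
  s <- params$step
  res <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    len <- unname(genome[ci])
    if (len < W) next
    starts <- seq(0, len - W, by = s)
    u <- uni[uni$chrom == chrom, , drop = FALSE]
    covered <- .covered_upto(u$start, u$end, starts + W) -
      .covered_upto(u$start, u$end, starts)
    res[[ci]] <- data.frame(chrom = chrom, start = starts, end = starts + W,
                            covered_bp = covered, fraction = covered / W,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), covered_bp = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  .sort_features(out)
}

#' Call dense repeat arrays from a window scan
#'
#' A window qualifies iff its covered fraction strictly exceeds
#' `min_density` (the screen is ">70%"). Overlapping or book-ended
#' qualifying windows on a chromosome are merged; the region span is the
#' union span (`[min start, max end]`) of its windows — boundaries are not
#' trimmed to repeat edges, so the reported, recomputed density over the
#' span is informative, not re-filtered, and may fall below `min_density`
#' when merged flanks dilute it. Regions are kept iff span `>= min_length`
#' (a single qualifying window spans exactly W = L and is a valid call).
#'
#' @param windows output of [window_scan()] run with the same `params`.
#' @param params the [scan_params()] used for the scan.
#' @param repeats optional repeat data frame used to recompute each region's
#'   density over its span (union of class-filtered features); if omitted
#'   the `density` column is NA.
#' @return data frame with `id`, `chrom`, `start`, `end`, `length`,
#'   `density`, `n_windows`, sorted by (chrom, start).
#' @export
call_arrays <- function(windows, params = scan_params(), repeats = NULL) {
  stopifnot(inherits(params, "scan_params"))
  empty <- data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      density = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  q <- windows[windows$fraction > params$min_density, , drop = FALSE]
  if (NROW(q) == 0L) return(empty)
  q <- .sort_features(q)
  regions <- list()
  for (chrom in unique(q$chrom)) {
    qc <- q[q$chrom == chrom, , drop = FALSE]
    cur_start <- qc$start[1]
    cur_end <- qc$end[1]
    nwin <- 1L
    flush <- function(s, e, nw) {
      regions[[length(regions) + 1L]] <<-
        data.frame(chrom = chrom, start = s, end = e, length = e - s,
                   n_windows = nw, stringsAsFactors = FALSE)
    }
    for (i in seq_len(NROW(qc))[-1]) {
      if (qc$start[i] <= cur_end) {       # overlapping or book-ended
        cur_end <- max(cur_end, qc$end[i])
        nwin <- nwin + 1L
      } else {
        flush(cur_start, cur_end, nwin)
        cur_start <- qc$start[i]
        cur_end <- qc$end[i]
        nwin <- 1L
      }
    }
    flush(cur_start, cur_end, nwin)
  }
  out <- do.call(rbind, regions)
  out <- out[out$length >= params$min_length, , drop = FALSE]
  if (NROW(out) == 0L) return(empty)
  out <- .sort_features(out)
  density <- rep(NA_real_, NROW(out))
  if (!is.null(repeats)) {
    keep <- params$class_filter(repeats)
    uni <- union_intervals(repeats[keep, c("chrom", "start", "end"),
                                   drop = FALSE])
    for (i in seq_len(NROW(out))) {
      u <- uni[uni$chrom == out$chrom[i] & uni$start < out$end[i] &
                 uni$end > out$start[i], , drop = FALSE]
      density[i] <- coverage_fraction(u, out[i, ])
    }
  }
  data.frame(id = sprintf("%s:%s-%s", out$chrom,
                          format(out$start, scientific = FALSE, trim = TRUE),
                          format(out$end, scientific = FALSE, trim = TRUE)),
             chrom = out$chrom, start = out$start, end = out$end,
             length = out$length, density = density,
             n_windows = out$n_windows, stringsAsFactors = FALSE)
}

#' Repeat composition of an interval
#'
#' Per repeat class, the fraction of the interval covered by the union of
#' that class's features; the total interspersed fraction is the union over
#' all classes (never more than 1, never less than the largest per-class
#' fraction, and generally less than the per-class sum because classes can
#' overlap).
#'
#' @param interval a single interval (data frame row or list with `chrom`,
#'   `start`, `end`).
#' @param repeats repeat data frame.
#' @return data frame of class `composition_summary` with `rep_class`,
#'   `covered_bp`, `fraction` (classes sorted by decreasing fraction), and
#'   attributes `total_fraction`, `total_covered_bp`, `interval_length`.
#' @export
region_composition <- function(interval, repeats) {
  w <- data.frame(chrom = as.character(interval$chrom[[1]]),
                  start = as.numeric(interval$start[[1]]),
                  end = as.numeric(interval$end[[1]]),
                  stringsAsFactors = FALSE)
  len <- w$end - w$start
  if (len <= 0) stop("zero-length interval")
  classes <- sort(unique(repeats$rep_class), method = "radix")
  covered <- vapply(classes, function(cl) {
    intersect_length(repeats[repeats$rep_class == cl,
                             c("chrom", "start", "end"), drop = FALSE], w)
  }, 0)
  out <- data.frame(rep_class = classes, covered_bp = unname(covered),
                    fraction = unname(covered) / len,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$rep_class, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  total <- intersect_length(repeats[, c("chrom", "start", "end"),
                                    drop = FALSE], w)
  structure(out, class = c("composition_summary", "data.frame"),
            total_fraction = total / len, total_covered_bp = total,
            interval_length = len)
}
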