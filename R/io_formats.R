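# Readers/writers for the external formats the pipeline touches. Everything
# is normalized on read to 0-based half-open coordinates and sorted by
# (chrom, start, end); invalid coordinates are rejected at parse time with
# the offending line number, never silently clipped.

.repeat_cols <- c("chrom", "start", "end", "strand", "rep_name", "rep_class",
                  "rep_family", "lineage", "divergence")

.validate_against_genome <- function(df, genome, path = "<features>") {
  if (is.null(genome) || NROW(df) == 0L) return(invisible(df))
  stopifnot(inherits(genome, "genome_map"))
  unknown <- setdiff(unique(as.character(df$chrom)), names(genome))
  if (length(unknown)) {
    stop(path, ": features on chromosome(s) absent from the genome map: ",
         paste(unknown, collapse = ", "))
  }
  lim <- unname(genome[as.character(df$chrom)])
  bad <- which(df$end > lim)
  if (length(bad)) {
    stop(sprintf("%s: feature %s:%s-%s exceeds chromosome length %s", path,
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]],
                 lim[bad[1]]))
  }
  invisible(df)
}

.nonempty_lines <- function(path, skip_comment = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (skip_comment) keep <- keep & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], line_no = which(keep))
}

#' Read repeat annotations
#'
#' Supported dialects:
#' \describe{
#'   \item{`rmsk_out`}{RepeatMasker `.out`: three header lines, then 14+
#'     whitespace-separated columns. Query coordinates are 1-based inclusive
#'     and converted by `start <- begin - 1`; strand `C` becomes `-`; the
#'     class/family column (`LINE/L1`) is split on `/`. Lines flagged `*`
#'     (overlapping a better match) are kept: downstream coverage is computed
#'     on interval unions, so double annotation is harmless.}
#'   \item{`ucsc_rmsk`}{UCSC `rmsk` table dump, tab-separated, `genoStart`
#'     already 0-based half-open. Both the 17-column (leading `bin`) and
#'     16-column layouts are accepted; `#`-comment lines are skipped.}
#'   \item{`bed`}{BED with the name column carrying `name|class|family`.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"ucsc_rmsk"`, `"rmsk_out"`, `"bed"`.
#' @param genome optional [genome_map()]; features on chromosomes absent from
#'   it, or running past a chromosome end, raise an error (not dropped).
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class`, `rep_family`, `lineage` (NA until assigned),
#'   `divergence` (milliDiv, NA if absent), sorted by (chrom, start, end).
#' @export
read_repeats <- function(path, dialect = c("ucsc_rmsk", "rmsk_out", "bed"),
                         genome = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "rmsk_out") {
    # the standard .out header is three raw lines (two label rows + blank)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readLines(path, warn = FALSE)
    if (length(raw) < 3L) stop(path, ": missing rmsk .out header lines")
    keep <- seq_along(raw) > 3L & nzchar(trimws(raw))
    lines <- raw[keep]
    line_no <- which(keep)
  } else {
    src <- .nonempty_lines(path)
    lines <- src$lines
    line_no <- src$line_no
  }
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[[i]]), if (dialect == "bed") "[ \t]+" else
      if (dialect == "ucsc_rmsk") "\t" else "[ \t]+")[[1]]
    rec <- switch(dialect,
      rmsk_out = {
        if (length(f) < 14L) {
          stop(sprintf("%s line %d: expected >=14 columns", path, line_no[i]))
        }
        cf <- strsplit(f[[11]], "/", fixed = TRUE)[[1]]
        list(chrom = f[[5]],
             start = suppressWarnings(as.numeric(f[[6]])) - 1,
             end = suppressWarnings(as.numeric(f[[7]])),
             strand = if (f[[9]] == "C") "-" else f[[9]],
             rep_name = f[[10]],
             rep_class = cf[[1]],
             rep_family = if (length(cf) > 1L) cf[[2]] else cf[[1]],
             divergence = round(suppressWarnings(as.numeric(f[[2]])) * 10))
      },
      ucsc_rmsk = {
        off <- if (length(f) >= 17L) 1L else 0L    # leading bin column
        if (length(f) < 12L + off) {
          stop(sprintf("%s line %d: expected a UCSC rmsk row", path,
                       line_no[i]))
        }
        list(chrom = f[[5L + off]],
             start = suppressWarnings(as.numeric(f[[6L + off]])),
             end = suppressWarnings(as.numeric(f[[7L + off]])),
             strand = f[[9L + off]],
             rep_name = f[[10L + off]],
             rep_class = f[[11L + off]],
             rep_family = f[[12L + off]],
             divergence = suppressWarnings(as.numeric(f[[2L + off]])))
      },
      bed = {
        if (length(f) < 4L) {
          stop(sprintf("%s line %d: repeat BED needs >=4 columns", path,
                       line_no[i]))
        }
        parts <- strsplit(f[[4]], "|", fixed = TRUE)[[1]]
        if (length(parts) < 2L) {
          stop(sprintf("%s line %d: name column must be name|class|family",
                       path, line_no[i]))
        }
        list(chrom = f[[1]],
             start = suppressWarnings(as.numeric(f[[2]])),
             end = suppressWarnings(as.numeric(f[[3]])),
             strand = if (length(f) >= 6L && f[[6]] %in% c("+", "-"))
               f[[6]] else "unknown",
             rep_name = parts[[1]],
             rep_class = parts[[2]],
             rep_family = if (length(parts) > 2L) parts[[3]] else parts[[2]],
             divergence = NA_real_)
      })
    if (is.na(rec$start) || is.na(rec$end)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, line_no[i]))
    }
    if (rec$end <= rec$start || rec$start < 0) {
      stop(sprintf("%s line %d: end <= start after coordinate conversion",
                   path, line_no[i]))
    }
    if (!nzchar(rec$rep_class)) {
      stop(sprintf("%s line %d: empty repeat class", path, line_no[i]))
    }
    if (!rec$strand %in% c("+", "-")) rec$strand <- "unknown"
    out[[i]] <- rec
  }
  df <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    rep_name = vapply(out, `[[`, "", "rep_name"),
    rep_class = vapply(out, `[[`, "", "rep_class"),
    rep_family = vapply(out, `[[`, "", "rep_family"),
    lineage = NA_character_,
    divergence = vapply(out, `[[`, 0, "divergence"),
    stringsAsFactors = FALSE
  )
  if (n == 0L) df <- df[0, ]
  .validate_against_genome(df, genome, path)
  .sort_features(df)
}

#' Read a BED3/BED6 track
#'
#' Used for genes, LAD tracks and generic region lists. Coordinates are
#' 0-based half-open per the BED standard; zero-length intervals are allowed
#' (some LAD dumps contain them), `start > end` is an error.
#'
#' @param path BED file.
#' @param genome optional [genome_map()] for validation.
#' @return sorted data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with NA).
#' @export
read_bed_track <- function(path, genome = NULL) {
  src <- .nonempty_lines(path)
  lines <- src$lines
  line_no <- src$line_no
  lines_keep <- !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[lines_keep]
  line_no <- line_no[lines_keep]
  n <- length(lines)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  name <- rep(NA_character_, n); score <- rep(NA_real_, n)
  strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) < 3L) {
      stop(sprintf("%s line %d: BED needs at least 3 columns", path,
                   line_no[i]))
    }
    s <- suppressWarnings(as.numeric(f[[2]]))
    e <- suppressWarnings(as.numeric(f[[3]]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, line_no[i]))
    }
    if (s > e || s < 0) {
      stop(sprintf("%s line %d: start > end", path, line_no[i]))
    }
    chrom[i] <- f[[1]]; start[i] <- s; end[i] <- e
    if (length(f) >= 4L) name[i] <- f[[4]]
    if (length(f) >= 5L) score[i] <- suppressWarnings(as.numeric(f[[5]]))
    if (length(f) >= 6L) strand[i] <- f[[6]]
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, stringsAsFactors = FALSE)
  .validate_against_genome(df, genome, path)
  .sort_features(df)
}

#' Write intervals as BED
#'
#' @param x data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(x, path) {
  .check_intervals(x)
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cols <- list(x$chrom, fmt(x$start), fmt(x$end))
  if (!is.null(x$name)) {
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
    if (!is.null(x$score)) {
      cols <- c(cols, list(ifelse(is.na(x$score), "0", fmt(x$score))))
      if (!is.null(x$strand)) {
        cols <- c(cols, list(ifelse(is.na(x$strand) |
                                      !x$strand %in% c("+", "-"),
                                    ".", x$strand)))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Write a called-array region report
#'
#' Emits a BED6 track (score = `round(density * 1000)`) and a TSV with one
#' row per region: chrom, start, end, length_bp, density, n_windows, context,
#' contained_genes, lad_status.
#'
#' @param regions data frame of called regions (see [call_arrays()]); the
#'   `context`, `contained_genes` and `lad_status` columns are optional.
#' @param path_bed,path_tsv output paths.
#' @return invisibly, a list with both paths.
#' @export
write_region_report <- function(regions, path_bed, path_tsv) {
  .check_intervals(regions, "region")
  n <- NROW(regions)
  get <- function(col, default) {
    if (!is.null(regions[[col]])) regions[[col]] else rep(default, n)
  }
  id <- get("id", if (n) sprintf("%s:%s-%s", regions$chrom,
                                format(regions$start, scientific = FALSE,
                                       trim = TRUE),
                                format(regions$end, scientific = FALSE,
                                       trim = TRUE)) else character())
  density <- as.numeric(get("density", NA_real_))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start,
                    end = regions$end,
                    name = id,
                    score = ifelse(is.na(density), 0, round(density * 1000)),
                    strand = rep(".", n),
                    stringsAsFactors = FALSE)
  write_bed_track(bed, path_bed)
  tsv <- data.frame(
    chrom = bed$chrom,
    start = format(bed$start, scientific = FALSE, trim = TRUE),
    end = format(bed$end, scientific = FALSE, trim = TRUE),
    length_bp = format(as.numeric(get("length",
                                      regions$end - regions$start)),
                       scientific = FALSE, trim = TRUE),
    density = sprintf("%.6f", density),
    n_windows = get("n_windows", NA_integer_),
    context = get("context", NA_character_),
    contained_genes = get("contained_genes", NA_character_),
    lad_status = get("lad_status", NA_character_),
    stringsAsFactors = FALSE
  )
  utils::write.table(tsv, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(list(bed = path_bed, tsv = path_tsv))
}
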