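#' Construct a genome map
#'
#' A genome map is an ordered chromosome name -> length (bp) table. It is the
#' coordinate reference every other stage validates against; iteration order
#' is preserved as given (file order for [read_chrom_sizes()]).
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return an object of class `genome_map` (a named numeric vector).
#' @export
genome_map <- function(lengths) {
  if (length(lengths) == 0L) stop("no chromosomes")
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) stop("all chromosomes must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  len <- as.numeric(lengths)
  if (any(!is.finite(len)) || any(len < 1) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(stats::setNames(len, nm), class = "genome_map")
}

#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns per non-empty line: chromosome name and
#' length in bp.
#'
#' @param path path to a chrom.sizes file.
#' @return a [genome_map()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  line_no <- which(keep)
  nm <- character(length(lines))
  len <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) < 2L) {
      stop(sprintf("%s line %d: expected two columns", path, line_no[i]))
    }
    v <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(v) || v != floor(v) || v <= 0) {
      stop(sprintf("%s line %d: chromosome length must be a positive integer",
                   path, line_no[i]))
    }
    nm[i] <- f[[1]]
    len[i] <- v
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("%s: duplicate chromosome name(s): %s", path,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  genome_map(stats::setNames(len, nm))
}

#' Write a genome map as a chrom.sizes file
#'
#' @param genome a [genome_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_map"))
  writeLines(paste0(names(genome), "\t",
                    format(unname(genome), scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome map with", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
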