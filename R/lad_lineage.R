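# Lamina-associated-domain overlap classification and repeat lineage
# stratification.

#' Classify regions by LAD overlap across cell types
#'
#' For each region and cell type, the LAD intervals of that cell type are
#' first unioned (adjacent fragments jointly satisfy the minimum-overlap
#' rule: the rule is about total lamina contact) and the region is counted
#' as lamina-associated in that cell type iff the intersection is at least
#' `min_overlap` bp. A region overlapping LADs in every cell type is
#' `CONSTITUTIVE`, in some but not all `FACULTATIVE`, otherwise `NONE`.
#'
#' @param regions data frame of regions (`chrom`, `start`, `end`, optional
#'   `id`).
#' @param lads named list of interval data frames, one per cell type (a LAD
#'   collection); must be non-empty with unique labels.
#' @param min_overlap minimum overlap in bp (default 10000, the 10-kb rule).
#' @return list of class `lad_call`: `records` (per region: id, comma-joined
#'   `overlapping_cell_types`, `n_cell_types`, `status`) and `summary`
#'   (`n_regions`, `n_any`, `n_constitutive`, `n_facultative`, `n_none`).
#' @export
lad_overlap <- function(regions, lads, min_overlap = 10000) {
  if (length(lads) == 0L) stop("empty LAD collection")
  if (is.null(names(lads)) || any(!nzchar(names(lads))) ||
      anyDuplicated(names(lads))) {
    stop("LAD tracks must carry unique cell-type labels")
  }
  stopifnot(min_overlap >= 1)
  n <- NROW(regions)
  id <- regions$id %||% sprintf("%s:%s-%s", regions$chrom,
                                format(regions$start, scientific = FALSE,
                                       trim = TRUE),
                                format(regions$end, scientific = FALSE,
                                       trim = TRUE))
  cts <- names(lads)
  hit <- matrix(FALSE, nrow = n, ncol = length(cts),
                dimnames = list(NULL, cts))
  for (ct in cts) {
    track <- union_intervals(lads[[ct]][, c("chrom", "start", "end"),
                                        drop = FALSE])
    for (i in seq_len(n)) {
      hit[i, ct] <- intersect_length(track, regions[i, c("chrom", "start",
                                                         "end")]) >=
        min_overlap
    }
  }
  n_ct <- rowSums(hit)
  status <- ifelse(n_ct == length(cts), "CONSTITUTIVE",
                   ifelse(n_ct > 0, "FACULTATIVE", "NONE"))
  if (n == 0L) status <- character(0)
  records <- data.frame(
    id = id,
    overlapping_cell_types = apply(hit, 1, function(z)
      paste(cts[z], collapse = ",")),
    n_cell_types = as.integer(n_ct),
    status = status,
    stringsAsFactors = FALSE
  )
  summary <- list(n_regions = n,
                  n_any = sum(n_ct > 0),
                  n_constitutive = sum(status == "CONSTITUTIVE"),
                  n_facultative = sum(status == "FACULTATIVE"),
                  n_none = sum(status == "NONE"))
  structure(list(records = records, summary = summary,
                 min_overlap = min_overlap, cell_types = cts),
            class = "lad_call")
}

#' @export
print.lad_call <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d region(s) vs %d cell type(s) (min overlap %s bp): %d any, %d constitutive, %d facultative, %d none\n",
    s$n_regions, length(x$cell_types),
    format(x$min_overlap, scientific = FALSE), s$n_any, s$n_constitutive,
    s$n_facultative, s$n_none))
  invisible(x)
}

.lineage_levels_default <- c("Eutherian", "Rodent", "Muridae", "Mus")

#' Repeat-name to lineage mapping
#'
#' A lineage map is an ordered prefix-rule table: the first rule whose
#' prefix matches a repeat name assigns the lineage; unmatched names are
#' `"unassigned"`. The default covers common mouse L1 subfamily prefixes
#' (`L1Md_*` = Mus; `Lx*` = Muridae; `L1_Mur*` = Rodent; `L1ME*`/`L1MB*` =
#' Eutherian); supply your own two-column TSV (prefix, lineage) for other
#' genomes. The ordered set of lineage labels is carried as the `levels`
#' attribute.
#'
#' @return data frame with `prefix`, `lineage` and a `levels` attribute.
#' @export
default_lineage_map <- function() {
  read_lineage_map(system.file("extdata", "lineage_map_mouse_l1.tsv",
                               package = "linescape", mustWork = TRUE))
}

#' @rdname default_lineage_map
#' @param path two-column TSV (prefix, lineage label); `#` comments allowed.
#' @param levels ordered lineage labels; defaults to the order of first
#'   appearance in the file.
#' @export
read_lineage_map <- function(path, levels = NULL) {
  src <- .nonempty_lines(path)
  rows <- strsplit(trimws(src$lines), "[ \t]+")
  bad <- which(lengths(rows) < 2L)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected two columns (prefix, lineage)", path,
                 src$line_no[bad[1]]))
  }
  map <- data.frame(prefix = vapply(rows, `[[`, "", 1L),
                    lineage = vapply(rows, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  structure(map, levels = levels %||% unique(map$lineage))
}

#' Assign lineages to repeat names
#'
#' @param rep_names character vector of repeat subfamily names.
#' @param lineage_map a lineage map (see [default_lineage_map()]).
#' @return character vector of lineage labels (`"unassigned"` when no rule
#'   matches).
#' @export
assign_lineage <- function(rep_names, lineage_map = default_lineage_map()) {
  out <- rep("unassigned", length(rep_names))
  todo <- rep(TRUE, length(rep_names))
  for (i in seq_len(NROW(lineage_map))) {
    m <- todo & startsWith(rep_names, lineage_map$prefix[i])
    out[m] <- lineage_map$lineage[i]
    todo[m] <- FALSE
  }
  out
}

#' Lineage-stratified repeat accounting inside vs outside arrays
#'
#' Counts elements per lineage genome-wide and splits them into
#' within-array vs outside-array strata. An element is within an array iff
#' its midpoint, `floor((start + end) / 2)`, falls inside a region — a rule
#' that prevents double counting of boundary-straddling elements. Ratios
#' are normalized to the first lineage label.
#'
#' @param repeats repeat data frame.
#' @param regions array regions (may be empty).
#' @param lineage_map a lineage map; element lineages are assigned from
#'   `rep_name` via its prefix rules.
#' @param element_filter predicate selecting the elements to count
#'   (default: L1-family repeats, [l1_filter()]).
#' @return data frame of class `lineage_table` with one row per lineage
#'   level: `lineage`, `count_genomewide`, `count_within_arrays`,
#'   `count_outside_arrays`, `ratio_genomewide`, `ratio_within_arrays`
#'   (within + outside = genomewide for every row); unmatched elements are
#'   reported via the `unassigned` attribute, not in the table.
#' @export
lineage_stratify <- function(repeats, regions,
                             lineage_map = default_lineage_map(),
                             element_filter = l1_filter()) {
  el <- repeats[element_filter(repeats), , drop = FALSE]
  lin <- assign_lineage(el$rep_name, lineage_map)
  mid <- floor((as.numeric(el$start) + as.numeric(el$end)) / 2)
  within <- rep(FALSE, NROW(el))
  if (NROW(el) > 0L && NROW(regions) > 0L) {
    sl <- sort(unique(c(el$chrom, regions$chrom)), method = "radix")
    pts <- data.frame(chrom = el$chrom, start = mid, end = mid + 1,
                      stringsAsFactors = FALSE)
    hits <- GenomicRanges::findOverlaps(.as_gr(pts, sl),
                                        .as_gr(regions, sl),
                                        ignore.strand = TRUE)
    within[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  levels <- attr(lineage_map, "levels") %||% unique(lineage_map$lineage)
  gw <- vapply(levels, function(l) sum(lin == l), 0)
  wi <- vapply(levels, function(l) sum(lin == l & within), 0)
  ratio <- function(x) if (x[1] > 0) x / x[1] else rep(NA_real_, length(x))
  out <- data.frame(lineage = levels,
                    count_genomewide = unname(gw),
                    count_within_arrays = unname(wi),
                    count_outside_arrays = unname(gw - wi),
                    ratio_genomewide = unname(ratio(gw)),
                    ratio_within_arrays = unname(ratio(wi)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("lineage_table", "data.frame"),
            unassigned = sum(lin == "unassigned"),
            unassigned_within = sum(lin == "unassigned" & within))
}
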