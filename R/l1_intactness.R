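# Simplified full-length LINE-1 intactness assessment: full-length status,
# ORF1/ORF2 integrity in the three forward frames, and a 3' poly(A)-signal
# check. Inputs are sense-oriented element extractions; reverse-strand
# scanning and alignment-based defect calling (gap detection against a
# consensus) are deliberately out of scope — a frameshift is detected only
# through its consequence, the loss of a qualifying ORF.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Thresholds for full-length L1 assessment
#'
#' Defaults sit near the canonical mouse L1 architecture (ORF1 ~40 kDa,
#' ORF2 ~150 kDa reverse transcriptase) and are deliberately configurable:
#' full-length databases use family-specific criteria that are not
#' reproduced here.
#'
#' @param expected_length consensus element length in bp.
#' @param full_length_fraction an element is full length iff its length is
#'   at least this fraction of `expected_length`.
#' @param orf1_min_aa,orf2_min_aa minimum ORF sizes in codons (ORF1 < ORF2).
#' @param orf1_search_window leading fraction of the element within which a
#'   qualifying ORF1 must start.
#' @param polya_signal poly(A) signal motif.
#' @param polya_window number of bases from the 3' end searched for the
#'   motif.
#' @return an object of class `element_spec`.
#' @export
element_spec <- function(expected_length = 6000, full_length_fraction = 0.95,
                         orf1_min_aa = 300, orf2_min_aa = 1200,
                         orf1_search_window = 0.45, polya_signal = "AATAAA",
                         polya_window = 60) {
  p <- list(expected_length = expected_length,
            full_length_fraction = full_length_fraction,
            orf1_min_aa = orf1_min_aa, orf2_min_aa = orf2_min_aa,
            orf1_search_window = orf1_search_window,
            polya_signal = toupper(polya_signal),
            polya_window = polya_window)
  stopifnot(p$expected_length > 0, p$full_length_fraction > 0,
            p$orf1_min_aa > 0, p$orf2_min_aa > 0,
            p$orf1_min_aa < p$orf2_min_aa,
            p$orf1_search_window > 0, p$orf1_search_window <= 1,
            nchar(p$polya_signal) > 0, p$polya_window > 0)
  structure(p, class = "element_spec")
}

#' Find open reading frames in the forward frames
#'
#' Scans the three forward frames for ORFs of at least `min_aa` codons
#' between an ATG and the next in-frame terminator. Terminators are stop
#' codons, codons containing an ambiguous base (N), and the end of the
#' frame (reported with `open_ended = TRUE`). Nested ORFs sharing a
#' terminator are collapsed to the longest (earliest ATG).
#'
#' @param seq DNA string over A/C/G/T/N (case-insensitive), sense
#'   orientation.
#' @param min_aa minimum ORF length in codons (the ATG counts as the first
#'   codon; the terminator does not count).
#' @return data frame with `start` (0-based nt offset), `end` (half-open;
#'   includes the stop codon when the ORF ends at one), `frame` (0/1/2),
#'   `length_aa`, `terminator` (`"stop"`, `"ambiguous"`, `"end"`),
#'   `open_ended`, sorted by `start`.
#' @export
find_orfs <- function(seq, min_aa = 1) {
  stopifnot(length(seq) == 1L, min_aa >= 1)
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- data.frame(start = numeric(), end = numeric(), frame = integer(),
                      length_aa = integer(), terminator = character(),
                      open_ended = logical(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-DNA characters")
  res <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    first <- f + 3L * (seq_len(ncod) - 1L) + 1L
    cods <- substring(s, first, first + 2L)
    is_stop <- cods %in% .stop_codons
    is_amb <- grepl("N", cods, fixed = TRUE)
    atg <- cods == "ATG"
    term_idx <- which(is_stop | is_amb)
    seg_start <- c(1L, term_idx + 1L)
    seg_term <- c(term_idx, ncod + 1L)
    for (j in seq_along(seg_start)) {
      lo <- seg_start[j]
      hi <- seg_term[j] - 1L
      if (hi < lo) next
      a_rel <- which(atg[lo:hi])
      if (length(a_rel) == 0L) next
      a <- lo + a_rel[1L] - 1L
      length_aa <- seg_term[j] - a
      if (length_aa < min_aa) next
      t_idx <- seg_term[j]
      terminator <- if (t_idx > ncod) "end"
        else if (is_stop[t_idx]) "stop" else "ambiguous"
      start_nt <- f + 3L * (a - 1L)
      end_nt <- start_nt + 3L * length_aa + if (terminator == "stop") 3L else 0L
      res[[length(res) + 1L]] <- data.frame(
        start = start_nt, end = end_nt, frame = f,
        length_aa = as.integer(length_aa), terminator = terminator,
        open_ended = terminator == "end", stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$frame, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess a putative full-length L1 element
#'
#' Applies four checks against an [element_spec()]:
#' \itemize{
#'   \item full length: element length >= `full_length_fraction *
#'     expected_length`;
#'   \item ORF1: an ORF of >= `orf1_min_aa` codons starting within the
#'     leading `orf1_search_window` fraction of the element (the longest
#'     such ORF is chosen, ties to the earliest start);
#'   \item ORF2: an ORF of >= `orf2_min_aa` codons starting at or after the
#'     chosen ORF1's stop (or after the search window when no ORF1 was
#'     found);
#'   \item poly(A) signal: the motif occurs within the final `polya_window`
#'     bases.
#' }
#' The element is intact iff all four hold; every failed check contributes
#' a defect string. Lowercase (soft-masked) bases are uppercased on input.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param spec an [element_spec()].
#' @param id element identifier carried into the report.
#' @return one-row data frame: `id`, `length`, `is_full_length`, `orf1_ok`,
#'   `orf2_ok`, `polya_ok`, `is_intact`, `defects` (semicolon-joined, empty
#'   when intact).
#' @export
assess_element <- function(seq, spec = element_spec(), id = NA_character_) {
  stopifnot(inherits(spec, "element_spec"))
  s <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-DNA characters")
  len <- nchar(s)
  defects <- character(0)

  is_full <- len >= spec$full_length_fraction * spec$expected_length
  if (!is_full) {
    defects <- c(defects, sprintf(
      "below full-length threshold (%d < %d bp)", len,
      ceiling(spec$full_length_fraction * spec$expected_length)))
  }

  orfs <- find_orfs(s, min_aa = min(spec$orf1_min_aa, spec$orf2_min_aa))
  w_nt <- floor(spec$orf1_search_window * len)
  cand1 <- orfs[orfs$length_aa >= spec$orf1_min_aa & orfs$start < w_nt, ,
                drop = FALSE]
  orf1_ok <- NROW(cand1) > 0L
  if (orf1_ok) {
    pick <- order(-cand1$length_aa, cand1$start)[1]
    orf1 <- cand1[pick, ]
  } else {
    defects <- c(defects, sprintf(
      "no intact ORF1 (>=%d aa) starting in the leading %d bp",
      spec$orf1_min_aa, w_nt))
  }

  bound <- if (orf1_ok) orf1$end else w_nt
  cand2 <- orfs[orfs$length_aa >= spec$orf2_min_aa & orfs$start >= bound, ,
                drop = FALSE]
  orf2_ok <- NROW(cand2) > 0L
  if (!orf2_ok) {
    defects <- c(defects, sprintf(
      "no intact ORF2 (>=%d aa) downstream of %s", spec$orf2_min_aa,
      if (orf1_ok) "ORF1" else "the ORF1 search window"))
  }

  tail_seq <- substring(s, max(1L, len - spec$polya_window + 1L), len)
  polya_ok <- grepl(spec$polya_signal, tail_seq, fixed = TRUE)
  if (!polya_ok) {
    defects <- c(defects, sprintf("no %s poly(A) signal within %d bp of 3' end",
                                  spec$polya_signal, spec$polya_window))
  }

  data.frame(id = id, length = len, is_full_length = is_full,
             orf1_ok = orf1_ok, orf2_ok = orf2_ok, polya_ok = polya_ok,
             is_intact = is_full && orf1_ok && orf2_ok && polya_ok,
             defects = paste(defects, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Assess every element in a FASTA file
#'
#' One record per element; the FASTA header (first word) is the element id.
#'
#' @param path FASTA file.
#' @param spec an [element_spec()].
#' @return data frame with one [assess_element()] row per record.
#' @export
assess_fasta <- function(path, spec = element_spec()) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    assess_element(as.character(seqs[[i]]), spec, id = ids[i])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- assess_element("ATG", spec)[0, ]
  }
  rownames(res) <- NULL
  res
}

#' Write an intactness report as TSV
#'
#' @param report data frame from [assess_fasta()] / [assess_element()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intactness_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
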