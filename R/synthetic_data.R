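# Seeded generators producing annotation bundles and L1 sequences with known
# ground truth. Repeat placement is a marked point process: element starts
# are drawn uniformly within a stratum (planted array or background gap) and
# elements accumulate until the union coverage of the stratum reaches its
# target fraction, so the controlled quantity is union coverage — matching
# how real RepeatMasker tracks behave, where fragments overlap freely.

.l1_name_pool <- list(
  Mus = c("L1Md_T", "L1Md_A", "L1Md_Gf", "L1Md_F2"),
  Muridae = c("Lx", "Lx2", "Lx3_Mus", "Lx5"),
  Rodent = c("L1_Mur1", "L1_Mur2", "L1_Mur3"),
  Eutherian = c("L1ME1", "L1ME3A", "L1MB5", "L1MB7")
)

.l1_div_range <- list(Mus = c(10, 120), Muridae = c(120, 200),
                      Rodent = c(200, 280), Eutherian = c(280, 380))

.other_class_meta <- list(
  SINE = list(names = c("B1_Mus1", "B1_Mm", "B2_Mm1a", "B2_Mm2"),
              family = "B1", mean_length = 150),
  LTR = list(names = c("RLTR10", "IAPEz-int", "MTA_Mm"),
             family = "ERVK", mean_length = 400)
)

#' Configuration of the synthetic annotation generator
#'
#' Defaults describe the reference validation landscape: a 5-Mb chromosome
#' with 20% background LINE coverage and ten planted 150-kb arrays at 85%
#' coverage — the regime the genome-wide screen (>70% LINE over >100 kb)
#' must recover. The within-array lineage mixture defaults to the skew
#' observed in real arrays (Eutherian:Rodent:Muridae:Mus near
#' 372:747:2004:2800) and the background mixture to the genome-wide
#' near-1:1:1:1 ratio.
#'
#' @param genome named vector of chromosome lengths (passed to
#'   [genome_map()]).
#' @param background_density target LINE coverage fraction p0 outside
#'   arrays.
#' @param array_density target LINE coverage fraction p1 inside planted
#'   arrays.
#' @param repeat_mean_length geometric mean LINE element length in bp.
#' @param n_arrays,array_length planted array count and length (bp).
#' @param min_array_gap minimum distance between planted arrays (and to
#'   chromosome ends), so that distinct arrays remain resolvable by a
#'   window scan.
#' @param array_lineage_mix,background_lineage_mix per-stratum lineage
#'   proportions (must sum to 1); labels must be lineage-map labels.
#' @param other_class_density named vector of additional repeat-class
#'   coverage fractions (applied uniformly in both strata) for composition
#'   realism; set to `NULL` for LINE-only annotations.
#' @param n_background_genes,gene_mean_length background gene count and
#'   mean length.
#' @param cluster_family gene-name prefix of the tandem cluster family.
#' @param n_clusters,cluster_size expected number of tandem clusters (the
#'   realized count is Poisson-distributed, making placement a homogeneous
#'   point process) and genes per cluster.
#' @param cluster_gene_length,cluster_gene_gap cluster geometry in bp.
#' @param cluster_enrichment_factor relative placement density of clusters
#'   inside arrays vs outside: a cluster is placed inside an array with
#'   probability `ef*a / (ef*a + 1 - a)` where `a` is the array fraction of
#'   the genome. `ef = 1` is the null configuration (placement independent
#'   of arrays); `ef = 10` plants clusters at 10x the background rate.
#' @param lad_cell_types cell-type labels for the LAD tracks.
#' @param lad_cover_prob per-cell-type probability that a planted array is
#'   covered by a LAD (scalar recycled).
#' @param n_background_lads,background_lad_length background LADs per cell
#'   type, placed away from arrays.
#' @param lad_buffer exclusion margin (bp) around planted arrays for
#'   background LADs, so the planted LAD truth stays identifiable at
#'   window-scan boundary resolution.
#' @param lad_extension_max planted-array LADs extend beyond the array by
#'   up to this many bp on each side.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome = c(chrS = 5e6),
                       background_density = 0.20,
                       array_density = 0.85,
                       repeat_mean_length = 600,
                       n_arrays = 10,
                       array_length = 150000,
                       min_array_gap = 200000,
                       array_lineage_mix =
                         c(Eutherian = 372, Rodent = 747,
                           Muridae = 2004, Mus = 2800) / 5923,
                       background_lineage_mix =
                         c(Eutherian = 0.25, Rodent = 0.25,
                           Muridae = 0.25, Mus = 0.25),
                       other_class_density = c(SINE = 0.05, LTR = 0.03),
                       n_background_genes = 100,
                       gene_mean_length = 2000,
                       cluster_family = "Olfr",
                       n_clusters = 10,
                       cluster_size = 6,
                       cluster_gene_length = 1500,
                       cluster_gene_gap = 500,
                       cluster_enrichment_factor = 1,
                       lad_cell_types = c("ESC", "NPC", "AST", "MEF"),
                       lad_cover_prob = c(0.9, 0.9, 0.5, 0.5),
                       n_background_lads = 4,
                       background_lad_length = 200000,
                       lad_buffer = 50000,
                       lad_extension_max = 40000) {
  gm <- genome_map(genome)
  cfg <- as.list(environment())
  cfg$genome <- gm
  for (p in c("background_density", "array_density")) {
    v <- cfg[[p]]
    if (v < 0 || v > 1) stop(p, " must lie in [0, 1]")
  }
  for (p in c("array_lineage_mix", "background_lineage_mix")) {
    v <- cfg[[p]]
    if (is.null(names(v)) || abs(sum(v) - 1) > 1e-6 || any(v < 0)) {
      stop(p, " must be a named non-negative vector summing to 1")
    }
    cfg[[p]] <- v / sum(v)
  }
  prob <- rep_len(cfg$lad_cover_prob, length(cfg$lad_cell_types))
  names(prob) <- cfg$lad_cell_types
  if (any(prob < 0 | prob > 1)) stop("lad_cover_prob must lie in [0, 1]")
  cfg$lad_cover_prob <- prob
  if (cfg$n_arrays > 0 && cfg$array_length > max(gm)) {
    stop("array_length exceeds every chromosome")
  }
  need <- cfg$n_arrays * (cfg$array_length + cfg$min_array_gap)
  if (need > sum(gm)) {
    stop("planted arrays do not fit inside the genome without overlap")
  }
  structure(cfg, class = "sim_config")
}

# Union length of raw intervals via a sort-and-scan; the generator calls
# this inside tight placement loops where S4 container overhead would
# dominate. The public interval API (union_intervals etc.) remains the
# IRanges-backed route and is cross-checked against per-base oracles.
.union_len_base <- function(starts, ends) {
  if (length(starts) == 0L) return(0)
  o <- order(starts)
  s <- starts[o]
  e <- ends[o]
  hi <- cummax(e)
  lag <- c(-Inf, hi[-length(hi)])
  sum(pmax(0, e - pmax(s, lag)))
}

# Coverage of [s, e) by the union of a feature subset, base-R route.
.coverage_base <- function(feats, chrom, s, e) {
  sel <- feats$chrom == chrom & feats$start < e & feats$end > s
  if (!any(sel)) return(0)
  .union_len_base(pmax(feats$start[sel], s), pmin(feats$end[sel], e)) /
    (e - s)
}

# Fill [s, e) with elements until union coverage reaches target_p * (e - s).
# Elements are clipped to the stratum, so strata stay independent.
.fill_interval <- function(s, e, target_p, mean_len) {
  len <- e - s
  out <- data.frame(start = numeric(), end = numeric())
  if (target_p <= 0 || len <= 0) return(out)
  if (target_p >= 1) return(data.frame(start = s, end = e))
  target <- target_p * len
  starts <- numeric(0)
  ends <- numeric(0)
  cur <- 0
  while (cur < target) {
    need <- target - cur
    m <- if (need < 5 * mean_len) 1L else
      max(1L, min(as.integer(ceiling(need / mean_len)), 5000L))
    st <- s + floor(stats::runif(m) * len)
    le <- stats::rgeom(m, 1 / mean_len) + 1
    en <- pmin(st + le, e)
    starts <- c(starts, st)
    ends <- c(ends, en)
    cur <- .union_len_base(starts, ends)
  }
  data.frame(start = starts, end = ends)
}

.realized_coverage <- function(repeats, interval, classes = "LINE") {
  feats <- repeats[repeats$rep_class %in% classes, , drop = FALSE]
  .coverage_base(feats, as.character(interval$chrom[[1]]),
                 as.numeric(interval$start[[1]]),
                 as.numeric(interval$end[[1]]))
}

#' Simulate an annotation bundle with known truth
#'
#' Places non-overlapping LINE-dense arrays on the genome, fills arrays and
#' background with LINE elements to their target union coverages (realized
#' values are recorded in the truth set), assigns per-element lineages from
#' the stratum mixture, places background genes and tandem gene clusters
#' (enriched into arrays per the configuration), and builds per-cell-type
#' LAD tracks covering a random subset of arrays. Identical
#' (configuration, seed) pairs produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param dir optional output directory; when given, the bundle is written
#'   as `chrom.sizes`, `repeats.tsv` (UCSC rmsk layout), `genes.bed`,
#'   `lad_<celltype>.bed` and `truth.json`.
#' @return list of class `annotation_sim`: `genome`, `repeats`, `genes`,
#'   `lads` (named list of interval data frames), `truth` (planted arrays
#'   with realized densities and LAD status, per-gene labels, per-cell-type
#'   covered arrays, realized background density), `files`, `config`,
#'   `seed`.
#' @export
simulate_annotation <- function(config, seed, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gm <- config$genome
  res <- withr::with_seed(as.integer(seed), {
    ## ---- planted arrays -------------------------------------------------
    # exact placement: assign arrays to chromosomes within capacity, then
    # distribute the per-chromosome slack uniformly between ordered arrays,
    # guaranteeing min_array_gap separation (also from chromosome ends)
    alen <- config$array_length
    gap <- config$min_array_gap
    lens <- as.numeric(gm)
    cap <- pmax(0, floor((lens - gap) / (alen + gap)))
    counts <- integer(length(gm))
    for (i in seq_len(config$n_arrays)) {
      w <- ifelse(cap - counts > 0, lens, 0)
      if (all(w == 0)) {
        stop("planted arrays do not fit inside the genome without overlap")
      }
      ci <- if (length(gm) == 1L) 1L else sample.int(length(gm), 1L,
                                                     prob = w)
      counts[ci] <- counts[ci] + 1L
    }
    arr <- list()
    for (ci in seq_along(gm)) {
      k <- counts[ci]
      if (k == 0L) next
      slack <- lens[ci] - k * alen - (k + 1) * gap
      cuts <- floor(sort(stats::runif(k)) * slack)
      starts <- gap + cuts + (seq_len(k) - 1L) * (alen + gap)
      arr[[ci]] <- data.frame(chrom = names(gm)[ci], start = starts,
                              end = starts + alen, stringsAsFactors = FALSE)
    }
    arr <- .sort_features(do.call(rbind, arr))
    arr$id <- sprintf("array_%02d", seq_len(NROW(arr)))

    ## ---- background gaps (complement of arrays, per chromosome) ---------
    gaps <- list()
    for (ci in seq_along(gm)) {
      chrom <- names(gm)[ci]
      a <- arr[arr$chrom == chrom, , drop = FALSE]
      bounds <- c(0, as.vector(rbind(a$start, a$end)), unname(gm[ci]))
      for (j in seq(1, length(bounds), by = 2)) {
        if (bounds[j + 1] > bounds[j]) {
          gaps[[length(gaps) + 1L]] <- data.frame(
            chrom = chrom, start = bounds[j], end = bounds[j + 1],
            stringsAsFactors = FALSE)
        }
      }
    }
    gaps <- do.call(rbind, gaps)

    ## ---- repeats --------------------------------------------------------
    mk_elements <- function(iv, target_p, mean_len, stratum) {
      pieces <- lapply(seq_len(NROW(iv)), function(k) {
        d <- .fill_interval(iv$start[k], iv$end[k], target_p, mean_len)
        if (NROW(d)) d$chrom <- iv$chrom[k]
        d
      })
      d <- do.call(rbind, pieces[vapply(pieces, NROW, 0L) > 0])
      if (is.null(d)) return(NULL)
      d$stratum <- stratum
      d
    }
    line_arr <- mk_elements(arr, config$array_density,
                            config$repeat_mean_length, "array")
    line_bg <- mk_elements(gaps, config$background_density,
                           config$repeat_mean_length, "background")
    lines_df <- rbind(line_arr, line_bg)
    rep_rows <- list()
    if (!is.null(lines_df) && NROW(lines_df)) {
      mix_of <- function(stratum) {
        if (stratum == "array") config$array_lineage_mix else
          config$background_lineage_mix
      }
      lineage <- character(NROW(lines_df))
      for (str in unique(lines_df$stratum)) {
        sel <- lines_df$stratum == str
        mix <- mix_of(str)
        lineage[sel] <- sample(names(mix), sum(sel), replace = TRUE,
                               prob = mix)
      }
      nm <- character(length(lineage))
      div <- numeric(length(lineage))
      for (l in sort(unique(lineage), method = "radix")) {
        sel <- lineage == l
        nm[sel] <- sample(.l1_name_pool[[l]], sum(sel), replace = TRUE)
        r <- .l1_div_range[[l]]
        div[sel] <- round(stats::runif(sum(sel), r[1], r[2]))
      }
      rep_rows[["LINE"]] <- data.frame(
        chrom = lines_df$chrom, start = lines_df$start, end = lines_df$end,
        strand = sample(c("+", "-"), NROW(lines_df), replace = TRUE),
        rep_name = unname(nm), rep_class = "LINE", rep_family = "L1",
        lineage = lineage, divergence = unname(div),
        stringsAsFactors = FALSE)
    }
    for (cl in names(config$other_class_density %||% numeric())) {
      meta <- .other_class_meta[[cl]]
      if (is.null(meta)) {
        meta <- list(names = paste0(cl, "_sim"), family = cl,
                     mean_length = 300)
      }
      d <- rbind(mk_elements(arr, config$other_class_density[[cl]],
                             meta$mean_length, "array"),
                 mk_elements(gaps, config$other_class_density[[cl]],
                             meta$mean_length, "background"))
      if (is.null(d) || NROW(d) == 0L) next
      rep_rows[[cl]] <- data.frame(
        chrom = d$chrom, start = d$start, end = d$end,
        strand = sample(c("+", "-"), NROW(d), replace = TRUE),
        rep_name = sample(meta$names, NROW(d), replace = TRUE),
        rep_class = cl, rep_family = meta$family,
        lineage = NA_character_,
        divergence = round(stats::runif(NROW(d), 50, 300)),
        stringsAsFactors = FALSE)
    }
    repeats <- .sort_features(do.call(rbind, rep_rows) %||% data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      strand = character(), rep_name = character(), rep_class = character(),
      rep_family = character(), lineage = character(),
      divergence = numeric(), stringsAsFactors = FALSE))

    arr$realized_density <- vapply(seq_len(NROW(arr)), function(i) {
      .realized_coverage(repeats, arr[i, ])
    }, 0)
    bg_realized <- if (NROW(gaps)) {
      cov <- vapply(seq_len(NROW(gaps)), function(i) {
        .realized_coverage(repeats, gaps[i, ]) * (gaps$end[i] - gaps$start[i])
      }, 0)
      sum(cov) / sum(gaps$end - gaps$start)
    } else NA_real_

    ## ---- genes ----------------------------------------------------------
    gene_rows <- list()
    n_bg <- config$n_background_genes
    if (n_bg > 0) {
      glen <- pmax(200, stats::rgeom(n_bg, 1 / config$gene_mean_length) + 1)
      ci <- sample.int(length(gm), n_bg, replace = TRUE,
                       prob = as.numeric(gm))
      st <- floor(stats::runif(n_bg) * (as.numeric(gm)[ci] - glen))
      gene_rows[["bg"]] <- data.frame(
        chrom = names(gm)[ci], start = st, end = st + glen,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        name = sprintf("Gene%04d", seq_len(n_bg)), family = NA_character_,
        stringsAsFactors = FALSE)
    }
    # cluster placement by density-weighted rejection sampling: position
    # uniform over the genome (where the cluster fits the chromosome),
    # accepted with weight `ef` when the cluster falls fully inside a
    # planted array and weight 1 otherwise. ef = 1 is therefore exactly
    # the null (placement independent of arrays); ef > 1 plants clusters
    # into arrays at ef times the background rate.
    ef <- config$cluster_enrichment_factor
    span <- config$cluster_size * config$cluster_gene_length +
      (config$cluster_size - 1) * config$cluster_gene_gap
    fit_len <- pmax(0, as.numeric(gm) - span + 1)
    if (all(fit_len == 0)) stop("tandem cluster does not fit anywhere")
    max_w <- max(ef, 1)
    # Poisson-distributed realized count: cluster placement is then a
    # (weighted) homogeneous Poisson process, so successes of disjoint
    # regions are independent — the sampling model the binomial test
    # downstream assumes under the null.
    n_clusters_realized <- if (config$n_clusters > 0)
      stats::rpois(1, config$n_clusters) else 0L
    cluster_in_array <- logical(n_clusters_realized)
    gi <- 0L
    for (k in seq_len(n_clusters_realized)) {
      repeat {
        ci <- if (length(gm) == 1L) 1L else
          sample.int(length(gm), 1L, prob = fit_len)
        st <- floor(stats::runif(1) * fit_len[ci])
        in_arr <- any(arr$chrom == names(gm)[ci] & arr$start <= st &
                        st + span <= arr$end)
        w <- if (in_arr) ef else 1
        if (stats::runif(1) * max_w < w) break
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- st + (seq_len(config$cluster_size) - 1L) *
        (config$cluster_gene_length + config$cluster_gene_gap)
      gene_rows[[paste0("cl", k)]] <- data.frame(
        chrom = names(gm)[ci], start = starts,
        end = starts + config$cluster_gene_length, strand = strand,
        name = sprintf("%s%d", config$cluster_family,
                       100L + gi + seq_len(config$cluster_size)),
        family = config$cluster_family, stringsAsFactors = FALSE)
      gi <- gi + config$cluster_size
      cluster_in_array[k] <- in_arr
    }
    genes <- .sort_features(do.call(rbind, gene_rows) %||% data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      strand = character(), name = character(), family = character(),
      stringsAsFactors = FALSE))
    if (NROW(genes)) {
      genes$in_array <- vapply(seq_len(NROW(genes)), function(i) {
        any(arr$chrom == genes$chrom[i] & arr$start <= genes$start[i] &
              genes$end[i] <= arr$end)
      }, TRUE)
    } else {
      genes$in_array <- logical(0)
    }
    arr$has_cluster <- vapply(seq_len(NROW(arr)), function(i) {
      any(genes$family %in% config$cluster_family &
            genes$chrom == arr$chrom[i] & genes$start >= arr$start[i] &
            genes$end <= arr$end[i])
    }, TRUE)

    ## ---- LAD tracks -----------------------------------------------------
    lads <- list()
    covered <- list()
    for (ct in config$lad_cell_types) {
      q <- config$lad_cover_prob[[ct]]
      hit <- stats::runif(NROW(arr)) < q
      covered[[ct]] <- arr$id[hit]
      rows <- list()
      if (any(hit)) {
        a <- arr[hit, , drop = FALSE]
        e1 <- floor(stats::runif(NROW(a)) * (config$lad_extension_max + 1))
        e2 <- floor(stats::runif(NROW(a)) * (config$lad_extension_max + 1))
        rows[["arr"]] <- data.frame(
          chrom = a$chrom, start = pmax(0, a$start - e1),
          end = pmin(unname(gm[a$chrom]), a$end + e2),
          stringsAsFactors = FALSE)
      }
      if (config$n_background_lads > 0 && NROW(gaps)) {
        # keep lad_buffer clear of every planted array so the planted truth
        # stays exact even for regions called with window-resolution edges
        slack <- gaps
        slack$start <- slack$start +
          ifelse(slack$start > 0, config$lad_buffer, 0)
        slack$end <- slack$end -
          ifelse(slack$end < unname(gm[slack$chrom]), config$lad_buffer, 0)
        slack <- slack[slack$end - slack$start >= 1000, , drop = FALSE]
        for (b in seq_len(config$n_background_lads)) {
          L <- config$background_lad_length
          fit <- pmax(0, slack$end - slack$start - L + 1)
          if (all(fit == 0)) {
            L <- min(slack$end - slack$start)
            fit <- pmax(0, slack$end - slack$start - L + 1)
          }
          hi <- if (NROW(slack) == 1L) 1L else
            sample.int(NROW(slack), 1L, prob = fit)
          st <- slack$start[hi] + floor(stats::runif(1) * fit[hi])
          rows[[paste0("bg", b)]] <- data.frame(
            chrom = slack$chrom[hi], start = st, end = st + L,
            stringsAsFactors = FALSE)
        }
      }
      lads[[ct]] <- .sort_features(do.call(rbind, rows) %||% data.frame(
        chrom = character(), start = numeric(), end = numeric(),
        stringsAsFactors = FALSE))
    }
    n_ct <- vapply(arr$id, function(id) {
      sum(vapply(covered, function(ids) id %in% ids, TRUE))
    }, 0L)
    arr$lad_status <- ifelse(n_ct == length(config$lad_cell_types),
                             "CONSTITUTIVE",
                             ifelse(n_ct > 0, "FACULTATIVE", "NONE"))

    list(arr = arr, repeats = repeats, genes = genes, lads = lads,
         covered = covered, bg_realized = bg_realized,
         cluster_in_array = cluster_in_array)
  })

  truth <- list(
    arrays = res$arr,
    background_realized_density = res$bg_realized,
    genes = if (NROW(res$genes))
      res$genes[, c("name", "family", "in_array")] else NULL,
    lad_covered_arrays = res$covered,
    cluster_in_array = res$cluster_in_array
  )
  files <- NULL
  if (!is.null(dir)) {
    files <- .write_sim_bundle(dir, gm, res$repeats, res$genes, res$lads,
                               truth)
  }
  structure(list(genome = gm, repeats = res$repeats, genes = res$genes,
                 lads = res$lads, truth = truth, files = files,
                 config = config, seed = as.integer(seed)),
            class = "annotation_sim")
}

.write_sim_bundle <- function(dir, gm, repeats, genes, lads, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$chrom_sizes <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(gm, files$chrom_sizes)
  files$repeats <- file.path(dir, "repeats.tsv")
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  con <- file(files$repeats, "w")
  writeLines(paste0("#bin\tswScore\tmilliDiv\tmilliDel\tmilliIns\tgenoName",
                    "\tgenoStart\tgenoEnd\tgenoLeft\tstrand\trepName",
                    "\trepClass\trepFamily\trepStart\trepEnd\trepLeft\tid"),
             con)
  if (NROW(repeats)) {
    writeLines(paste(0, 0, fmt(repeats$divergence), 0, 0, repeats$chrom,
                     fmt(repeats$start), fmt(repeats$end),
                     fmt(-(unname(gm[repeats$chrom]) - repeats$end)),
                     repeats$strand, repeats$rep_name, repeats$rep_class,
                     repeats$rep_family, 0, 0, 0, seq_len(NROW(repeats)),
                     sep = "\t"), con)
  }
  close(con)
  files$genes <- file.path(dir, "genes.bed")
  write_bed_track(
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               name = genes$name, score = 0, strand = genes$strand,
               stringsAsFactors = FALSE),
    files$genes)
  files$lads <- character(0)
  for (ct in names(lads)) {
    p <- file.path(dir, paste0("lad_", ct, ".bed"))
    write_bed_track(lads[[ct]], p)
    files$lads[ct] <- p
  }
  files$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files
}

#' @export
print.annotation_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic annotation: %d chrom(s), %d repeats, %d genes, %d LAD track(s), %d planted array(s) (seed %d)\n",
    length(x$genome), NROW(x$repeats), NROW(x$genes), length(x$lads),
    NROW(x$truth$arrays), x$seed))
  invisible(x)
}

#' Preset study configurations
#'
#' `fixture_config()` is the bundled end-to-end validation landscape: a 4-Mb
#' chromosome with six planted 150-kb arrays at 85% LINE coverage on a
#' repeat-free background, tandem clusters forced into a subset of arrays
#' and no background genes — a regime in which every pipeline summary count
#' is exactly determined by the generator truth (window-resolution region
#' boundaries cannot pick up stray background features).
#'
#' `enrichment_study_config()` is the gene-placement landscape used for
#' calibration and power studies of the cluster-enrichment test: fifty
#' 100-kb regions on an 80-Mb chromosome and an expected 480 six-gene
#' tandem clusters. The geometry is sized so that (i) the per-region
#' success probability is near one half, keeping the exact binomial test's
#' discreteness mild (with few regions the achievable tail sizes straddle
#' nominal levels too coarsely for a meaningful calibration check), and
#' (ii) the cluster field is dense relative to the region footprint, so
#' that the background success probability estimated from the same
#' dataset's random regions is nearly independent of the observed counts
#' (a sparse shared field correlates the two and makes the procedure
#' conservative). With
#' `enrichment_factor = 1` cluster placement is independent of the regions
#' (the null, type-I-error configuration); with `enrichment_factor = 10`
#' clusters are planted into regions at ten times the background rate.
#' Repeat tracks are not generated (densities 0): the test under study
#' consumes only regions and genes.
#'
#' @return a [sim_config()].
#' @export
fixture_config <- function() {
  sim_config(genome = c(chrF = 4e6),
             background_density = 0, array_density = 0.85,
             n_arrays = 6, array_length = 150000, min_array_gap = 200000,
             n_background_genes = 0, n_clusters = 4,
             cluster_enrichment_factor = 1e9,
             lad_cover_prob = c(0.9, 0.9, 0.5, 0.5))
}

#' @rdname fixture_config
#' @param enrichment_factor relative in-array cluster placement density
#'   (1 = null).
#' @export
enrichment_study_config <- function(enrichment_factor = 1) {
  sim_config(genome = c(chrE = 8e7),
             background_density = 0, array_density = 0,
             other_class_density = NULL,
             n_arrays = 50, array_length = 100000, min_array_gap = 50000,
             n_background_genes = 100, n_clusters = 480, cluster_size = 6,
             cluster_gene_length = 1500, cluster_gene_gap = 500,
             cluster_enrichment_factor = enrichment_factor)
}

## ---------------------------------------------------------------------------
## L1 sequence simulation

.codon_pool <- function() {
  all <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         c("A", "C", "G", "T"), paste0))
  setdiff(all, .stop_codons)
}

.sim_defects <- c("none", "substitution", "inject_stop_orf1",
                  "inject_stop_orf2", "frameshift", "truncate",
                  "mutate_polya")

.defect_target <- c(none = NA_character_, substitution = NA_character_,
                    inject_stop_orf1 = "orf1_ok",
                    inject_stop_orf2 = "orf2_ok", frameshift = "orf2_ok",
                    truncate = "is_full_length", mutate_polya = "polya_ok")

# Designed consensus layout. ORF2 starts just after the ORF1 search window,
# so that losing ORF1 does not also invalidate ORF2 under the
# "downstream of the search window" fallback; guard stop codons immediately
# 5' of each ORF prevent upstream in-frame extension from rescuing an
# injected stop.
.consensus_layout <- function(spec) {
  orf1_aa <- spec$orf1_min_aa + 50
  orf2_aa <- spec$orf2_min_aa + 80
  orf1_nt <- 3 * orf1_aa + 3
  orf2_nt <- 3 * orf2_aa + 3
  tail_len <- max(120, spec$polya_window + 30)
  f <- spec$orf1_search_window
  L <- ceiling((orf2_nt + tail_len + 9) / (1 - f))
  L <- max(L, ceiling(spec$full_length_fraction * spec$expected_length))
  w <- floor(f * L)
  s2 <- w + 3
  s1 <- 90
  stopifnot(s1 + orf1_nt + 3 < s2, s2 + orf2_nt + tail_len <= L)
  list(L = L, s1 = s1, orf1_aa = orf1_aa, s2 = s2, orf2_aa = orf2_aa,
       tail_len = tail_len)
}

.build_consensus <- function(spec, layout) {
  pool <- .codon_pool()
  v <- sample(c("A", "C", "G", "T"), layout$L, replace = TRUE)
  set_codon <- function(pos0, codon) {
    v[(pos0 + 1):(pos0 + 3)] <<- strsplit(codon, "")[[1]]
  }
  write_orf <- function(s, aa) {
    set_codon(s - 3, "TAA")                       # guard stop
    set_codon(s, "ATG")
    if (aa > 1) {
      body <- sample(pool, aa - 1, replace = TRUE)
      v[(s + 4):(s + 3 * aa)] <<- unlist(strsplit(body, ""))
    }
    set_codon(s + 3 * aa, "TAA")
  }
  write_orf(layout$s1, layout$orf1_aa)
  write_orf(layout$s2, layout$orf2_aa)
  # exactly one poly(A) signal inside the 3' search window
  pw <- spec$polya_window
  motif <- strsplit(spec$polya_signal, "")[[1]]
  ml <- length(motif)
  mpos0 <- layout$L - pw + floor((pw - ml) / 2)
  v[(mpos0 + 1):(mpos0 + ml)] <- motif
  repeat {
    win <- paste(v[(layout$L - pw + 1):layout$L], collapse = "")
    occ <- gregexpr(spec$polya_signal, win, fixed = TRUE)[[1]]
    occ <- occ[occ > 0]
    spurious <- occ[occ != (mpos0 - (layout$L - pw)) + 1]
    if (length(spurious) == 0L) break
    for (o in spurious) {
      idx <- (layout$L - pw) + o + seq_len(ml) - 1
      idx <- setdiff(idx, (mpos0 + 1):(mpos0 + ml))
      v[idx] <- sample(c("C", "G"), length(idx), replace = TRUE)
    }
  }
  v
}

#' Simulate L1 element sequences with controlled defects
#'
#' Builds a designed consensus meeting the [element_spec()] (codon-random,
#' stop-free ORFs of `orf1_min_aa + 50` and `orf2_min_aa + 80` codons, the
#' poly(A) signal placed once inside the 3' window) and emits `n` copies,
#' each carrying the defects listed in its defect plan at randomized
#' positions within the targeted span:
#' \describe{
#'   \item{`substitution`}{random substitutions at per-base rate `mu`.}
#'   \item{`inject_stop_orf1` / `inject_stop_orf2`}{an in-frame stop placed
#'     so that neither resulting fragment still qualifies.}
#'   \item{`frameshift`}{a 1-bp deletion early in ORF2.}
#'   \item{`truncate`}{keep the leading `truncate_fraction` of the element
#'     (5' truncations being how most genomic L1 copies arise).}
#'   \item{`mutate_polya`}{point-mutate the poly(A) signal.}
#' }
#'
#' @param n number of elements.
#' @param spec an [element_spec()].
#' @param defects per-element defect plan: `NULL` (all defect-free), a
#'   character vector recycled to length `n`, or a list of character
#'   vectors (multisets). Unknown defect names are an error.
#' @param mu substitution rate for the `substitution` defect.
#' @param truncate_fraction retained 5' fraction for `truncate`.
#' @param seed integer seed; output is deterministic per
#'   (arguments, seed).
#' @param path optional FASTA output path (one record per element, header =
#'   element id).
#' @return list of class `l1_sim`: `sequences` (named character vector),
#'   `consensus`, `truth` (data frame: `id`, `defects`, `target_flag` — the
#'   report flag each single defect is designed to break, NA for
#'   none/substitution), `spec`, `seed`, `path`.
#' @export
simulate_l1_fasta <- function(n, spec = element_spec(), defects = NULL,
                              mu = 0, truncate_fraction = 0.5, seed,
                              path = NULL) {
  stopifnot(inherits(spec, "element_spec"), n >= 1)
  plan <- if (is.null(defects)) rep(list(character(0)), n)
    else if (is.list(defects)) rep_len(defects, n)
    else as.list(rep_len(as.character(defects), n))
  plan <- lapply(plan, function(d) d[!d %in% c("", "none")])
  unknown <- setdiff(unique(unlist(plan)), .sim_defects)
  if (length(unknown)) {
    stop("unknown defect(s): ", paste(unknown, collapse = ", "))
  }
  layout <- .consensus_layout(spec)
  withr::with_seed(as.integer(seed), {
    cons <- .build_consensus(spec, layout)
    seqs <- character(n)
    for (i in seq_len(n)) {
      v <- cons
      d <- plan[[i]]
      if ("substitution" %in% d && mu > 0) {
        k <- stats::rbinom(1, length(v), mu)
        if (k > 0) {
          pos <- sample.int(length(v), k)
          for (p in pos) {
            v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
          }
        }
      }
      inject_stop <- function(v, s, aa, min_aa) {
        lo <- max(2L, aa - min_aa + 2L)
        hi <- min_aa - 1L
        j <- sample(lo:hi, 1L)
        v[(s + 3 * (j - 1) + 1):(s + 3 * (j - 1) + 3)] <- c("T", "A", "A")
        v
      }
      if ("inject_stop_orf1" %in% d) {
        v <- inject_stop(v, layout$s1, layout$orf1_aa, spec$orf1_min_aa)
      }
      if ("inject_stop_orf2" %in% d) {
        v <- inject_stop(v, layout$s2, layout$orf2_aa, spec$orf2_min_aa)
      }
      if ("mutate_polya" %in% d) {
        pw <- spec$polya_window
        win <- paste(v[(length(v) - pw + 1):length(v)], collapse = "")
        occ <- gregexpr(spec$polya_signal, win, fixed = TRUE)[[1]]
        occ <- occ[occ > 0]
        for (o in occ) {
          p <- (length(v) - pw) + o + 2L   # third motif base
          v[p] <- if (v[p] != "G") "G" else "C"
        }
      }
      if ("frameshift" %in% d) {
        # early in ORF2: both the truncated in-frame fragment and any
        # shifted-frame continuation stay far below the ORF2 threshold
        j <- sample(seq(layout$orf2_aa - spec$orf2_min_aa + 2L, 300L), 1L)
        p <- layout$s2 + 3 * (j - 1) + 1L
        v <- v[-p]
      }
      if ("truncate" %in% d) {
        v <- v[seq_len(max(1L, floor(truncate_fraction * length(v))))]
      }
      seqs[i] <- paste(v, collapse = "")
    }
    names(seqs) <- sprintf("L1sim_%03d", seq_len(n))
    truth <- data.frame(
      id = names(seqs),
      defects = vapply(plan, paste, "", collapse = ";"),
      target_flag = vapply(plan, function(d) {
        t <- unique(stats::na.omit(.defect_target[d]))
        if (length(t)) paste(t, collapse = ";") else NA_character_
      }, ""),
      stringsAsFactors = FALSE)
    if (!is.null(path)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                                  width = 70)
    }
    structure(list(sequences = seqs,
                   consensus = paste(cons, collapse = ""),
                   truth = truth, spec = spec, seed = as.integer(seed),
                   path = path),
              class = "l1_sim")
  })
}
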