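# End-to-end orchestration: scan -> call -> classify -> enrich -> LADs ->
# lineage (-> intactness when a FASTA is given), with a deterministic
# summary and a run log capturing every parameter and seed.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters. Referenced files are checked
#' at construction; the seed is mandatory because the enrichment stage is
#' randomized.
#'
#' @param repeats path to the repeat annotation file.
#' @param genome path to a chrom.sizes file.
#' @param dialect repeat dialect for [read_repeats()].
#' @param genes optional gene BED path.
#' @param lads optional named character vector of LAD BED paths (names =
#'   cell-type labels).
#' @param lineage_map optional path to a lineage-map TSV; default mapping
#'   used when NULL.
#' @param l1_fasta optional FASTA of L1 element sequences to assess.
#' @param params a [scan_params()].
#' @param family_patterns regexes of tandem gene families to test for
#'   enrichment.
#' @param n_random random regions per enrichment test.
#' @param min_lad_overlap minimum LAD overlap in bp.
#' @param l1_spec an [element_spec()] for the intactness stage.
#' @param seed integer seed (mandatory).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(repeats, genome,
                            dialect = c("ucsc_rmsk", "rmsk_out", "bed"),
                            genes = NULL, lads = NULL, lineage_map = NULL,
                            l1_fasta = NULL, params = scan_params(),
                            family_patterns = c("^Olfr", "^Vmn"),
                            n_random = 500, min_lad_overlap = 10000,
                            l1_spec = element_spec(),
                            seed) {
  dialect <- match.arg(dialect)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory (the enrichment stage is randomized)")
  }
  paths <- c(repeats = repeats, genome = genome, genes = genes, lads,
             lineage_map = lineage_map, l1_fasta = l1_fasta)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (!is.null(lads) &&
      (is.null(names(lads)) || any(!nzchar(names(lads))))) {
    stop("lads must be a named vector: celltype = path")
  }
  structure(list(repeats = repeats, genome = genome, dialect = dialect,
                 genes = genes, lads = lads, lineage_map = lineage_map,
                 l1_fasta = l1_fasta, params = params,
                 family_patterns = family_patterns,
                 n_random = n_random, min_lad_overlap = min_lad_overlap,
                 l1_spec = l1_spec, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full array-discovery pipeline
#'
#' Stages: read inputs, window scan, array calling, gene-context
#' classification, tandem-cluster enrichment (one test per family
#' pattern), LAD overlap classification, lineage stratification, and —
#' when an L1 FASTA is configured — intactness assessment. Writes
#' `regions.bed`/`regions.tsv`, `windows.bedgraph`, `enrichment.json`,
#' `lad_calls.tsv`, `lineage.tsv`, `intactness.tsv`, a `run_config.txt`
#' log and a `summary.json` holding every headline count. Output is
#' deterministic: two runs with an identical configuration are
#' byte-identical. A stage failure aborts with the stage name; partial
#' outputs are moved to a `quarantine/` subdirectory.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "setup"
  stage <- function(name) current_stage <<- name
  res <- tryCatch(
    .run_pipeline_stages(config, outdir, stage),
    error = function(e) {
      qdir <- file.path(outdir, "quarantine")
      dir.create(qdir, showWarnings = FALSE)
      produced <- setdiff(list.files(outdir, full.names = TRUE), qdir)
      file.rename(produced,
                  file.path(qdir, basename(produced)))
      stop("pipeline stage '", current_stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  invisible(res)
}

.run_pipeline_stages <- function(config, outdir, stage) {
  stage("read_inputs")
  genome <- read_chrom_sizes(config$genome)
  repeats <- read_repeats(config$repeats, config$dialect, genome = genome)
  genes <- if (!is.null(config$genes))
    read_bed_track(config$genes, genome = genome) else NULL
  lads <- if (!is.null(config$lads)) {
    lapply(stats::setNames(as.list(config$lads), names(config$lads)),
           read_bed_track, genome = genome)
  } else NULL
  lmap <- if (!is.null(config$lineage_map))
    read_lineage_map(config$lineage_map) else default_lineage_map()

  stage("window_scan")
  windows <- window_scan(repeats, genome, config$params)

  stage("call_arrays")
  regions <- call_arrays(windows, config$params, repeats)

  stage("classify_context")
  context <- NULL
  if (!is.null(genes)) {
    context <- classify_context(regions, genes)
    regions$context <- context$regions$context
    regions$contained_genes <- context$regions$contained_genes
  }

  stage("cluster_enrichment")
  enrichment <- list()
  if (!is.null(genes) && NROW(regions) > 0L) {
    for (pat in config$family_patterns) {
      enrichment[[pat]] <- cluster_enrichment(
        regions, genes, pat, genome, n_random = config$n_random,
        seed = config$seed)
    }
  }

  stage("lad_overlap")
  lad <- NULL
  if (!is.null(lads) && NROW(regions) > 0L) {
    lad <- lad_overlap(regions, lads, config$min_lad_overlap)
    regions$lad_status <- lad$records$status
  }

  stage("lineage_stratify")
  lineage <- lineage_stratify(repeats, regions, lmap)

  stage("l1_intactness")
  intact <- NULL
  if (!is.null(config$l1_fasta)) {
    intact <- assess_fasta(config$l1_fasta, config$l1_spec)
  }

  stage("write_outputs")
  write_region_report(regions, file.path(outdir, "regions.bed"),
                      file.path(outdir, "regions.tsv"))
  bg <- data.frame(chrom = windows$chrom,
                   start = format(windows$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(windows$end, scientific = FALSE,
                                trim = TRUE),
                   fraction = sprintf("%.6f", windows$fraction))
  utils::write.table(bg, file.path(outdir, "windows.bedgraph"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (length(enrichment)) {
    jsonlite::write_json(lapply(enrichment, unclass),
                         file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(
      do.call(rbind, lapply(enrichment, function(e)
        as.data.frame(unclass(e), stringsAsFactors = FALSE))),
      file.path(outdir, "enrichment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(lad)) {
    utils::write.table(lad$records, file.path(outdir, "lad_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(lineage),
                     file.path(outdir, "lineage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(intact)) {
    write_intactness_report(intact, file.path(outdir, "intactness.tsv"))
  }

  log_lines <- c(
    "linescape pipeline run",
    sprintf("seed: %d", config$seed),
    sprintf("repeats: %s (dialect %s)", config$repeats, config$dialect),
    sprintf("genome: %s", config$genome),
    sprintf("genes: %s", config$genes %||% "<none>"),
    sprintf("lads: %s", if (is.null(config$lads)) "<none>" else
      paste(sprintf("%s=%s", names(config$lads), config$lads),
            collapse = ", ")),
    sprintf("l1_fasta: %s", config$l1_fasta %||% "<none>"),
    sprintf("scan: preset=%s window=%d step=%d min_density=%g min_length=%d",
            config$params$preset, config$params$window, config$params$step,
            config$params$min_density, config$params$min_length),
    sprintf("enrichment: patterns=%s n_random=%d",
            paste(config$family_patterns, collapse = ","),
            as.integer(config$n_random)),
    sprintf("lad min_overlap: %d", as.integer(config$min_lad_overlap))
  )
  writeLines(log_lines, file.path(outdir, "run_config.txt"))

  per_chrom <- if (NROW(regions)) table(regions$chrom) else NULL
  summary <- list(
    seed = config$seed,
    n_windows = NROW(windows),
    n_regions = NROW(regions),
    regions_per_chrom = if (!is.null(per_chrom))
      as.list(stats::setNames(as.integer(per_chrom), names(per_chrom)))
      else NULL,
    context = if (!is.null(context))
      as.list(context$summary) else NULL,
    contains_genes_count = if (!is.null(context))
      context$contains_genes_count else NULL,
    enrichment = if (length(enrichment)) lapply(enrichment, unclass)
      else NULL,
    lad = if (!is.null(lad)) lad$summary else NULL,
    lineage = list(
      lineage = lineage$lineage,
      count_genomewide = lineage$count_genomewide,
      count_within_arrays = lineage$count_within_arrays,
      count_outside_arrays = lineage$count_outside_arrays),
    intactness = if (!is.null(intact)) list(
      n_elements = NROW(intact),
      n_full_length = sum(intact$is_full_length),
      n_intact = sum(intact$is_intact)) else NULL
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  summary
}
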