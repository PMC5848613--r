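small_cfg <- function(...) {
  sim_config(genome = c(chrS = 2e6), n_arrays = 4, array_length = 100000,
             min_array_gap = 150000, background_density = 0.2,
             array_density = 0.85, n_clusters = 3,
             n_background_genes = 30, ...)
}

test_that("identical (config, seed) produce byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  s1 <- simulate_annotation(cfg, seed = 31, dir = d1)
  s2 <- simulate_annotation(cfg, seed = 31, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  s3 <- simulate_annotation(cfg, seed = 32)
  expect_false(identical(s1$repeats, s3$repeats))
})

test_that("realized densities hit their targets within the audit tolerance", {
  cfg <- small_cfg()
  for (seed in c(41, 42, 43, 44, 45)) {
    sim <- simulate_annotation(cfg, seed = seed)
    expect_true(all(abs(sim$truth$arrays$realized_density - 0.85) <= 0.03))
    expect_lte(abs(sim$truth$background_realized_density - 0.20), 0.03)
  }
})

test_that("saturated arrays give fully covered windows", {
  cfg <- sim_config(genome = c(chrS = 1e6), n_arrays = 2,
                    array_length = 100000, min_array_gap = 120000,
                    background_density = 0.05, array_density = 1.0,
                    other_class_density = NULL, n_clusters = 1,
                    n_background_genes = 5)
  sim <- simulate_annotation(cfg, seed = 51)
  p <- scan_params(window = 20000, step = 20000, min_density = 0.5,
                   min_length = 20000)
  w <- window_scan(sim$repeats, sim$genome, p)
  arr <- sim$truth$arrays
  inside <- vapply(seq_len(NROW(w)), function(i) {
    any(arr$start <= w$start[i] & w$end[i] <= arr$end)
  }, TRUE)
  expect_true(all(w$fraction[inside] == 1))
})

test_that("emitted files parse cleanly and round-trip through io_formats", {
  d <- withr::local_tempdir()
  sim <- simulate_annotation(small_cfg(), seed = 61, dir = d)
  gm <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_identical(as.numeric(gm), as.numeric(sim$genome))
  reps <- read_repeats(file.path(d, "repeats.tsv"), "ucsc_rmsk",
                       genome = gm)
  expect_equal(reps[, c("chrom", "start", "end", "rep_name", "rep_class")],
               sim$repeats[, c("chrom", "start", "end", "rep_name",
                               "rep_class")])
  genes <- read_bed_track(file.path(d, "genes.bed"), genome = gm)
  expect_equal(NROW(genes), NROW(sim$genes))
  for (ct in names(sim$lads)) {
    lad <- read_bed_track(file.path(d, paste0("lad_", ct, ".bed")),
                          genome = gm)
    expect_equal(lad[, c("chrom", "start", "end")],
                 sim$lads[[ct]][, c("chrom", "start", "end")])
  }
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$arrays$start, sim$truth$arrays$start)
})

test_that("stored lineages agree with the shipped lineage map", {
  sim <- simulate_annotation(small_cfg(), seed = 71)
  l1 <- sim$repeats[sim$repeats$rep_class == "LINE", ]
  expect_equal(assign_lineage(l1$rep_name), l1$lineage)
})

test_that("cluster placement follows the enrichment factor", {
  # ef = 0 forces every cluster outside the arrays
  cfg0 <- small_cfg(cluster_enrichment_factor = 0)
  sim0 <- simulate_annotation(cfg0, seed = 81)
  expect_false(any(sim0$truth$cluster_in_array))
  fam0 <- sim0$genes[!is.na(sim0$genes$family), ]
  expect_false(any(fam0$in_array))
  # a huge factor forces every cluster inside
  cfg1 <- small_cfg(cluster_enrichment_factor = 1e9)
  sim1 <- simulate_annotation(cfg1, seed = 82)
  expect_true(all(sim1$truth$cluster_in_array))
  fam1 <- sim1$genes[!is.na(sim1$genes$family), ]
  expect_true(all(fam1$in_array))
  expect_true(all(startsWith(fam1$name, "Olfr")))
})

test_that("planted arrays respect separation and the truth is consistent", {
  sim <- simulate_annotation(small_cfg(), seed = 91)
  arr <- sim$truth$arrays
  expect_equal(arr$end - arr$start, rep(100000, 4))
  byc <- split(arr, arr$chrom)
  for (a in byc) {
    if (NROW(a) > 1) {
      expect_true(all(a$start[-1] - a$end[-NROW(a)] >= 150000))
    }
  }
  expect_true(all(arr$start >= 0 & arr$end <= unname(sim$genome[arr$chrom])))
})

test_that("L1 simulation is deterministic and validates its defect plan", {
  s1 <- simulate_l1_fasta(4, element_spec(), defects = "none", seed = 13)
  s2 <- simulate_l1_fasta(4, element_spec(), defects = "none", seed = 13)
  expect_identical(s1$sequences, s2$sequences)
  expect_true(all(s1$sequences == s1$consensus))
  expect_error(simulate_l1_fasta(1, element_spec(), defects = "explode",
                                 seed = 1), "unknown defect")
  tr <- simulate_l1_fasta(2, element_spec(), defects = "truncate",
                          truncate_fraction = 0.5, seed = 14)
  expect_equal(nchar(tr$sequences[[1]]),
               floor(0.5 * nchar(tr$consensus)))
  expect_equal(tr$truth$target_flag, rep("is_full_length", 2))
})
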