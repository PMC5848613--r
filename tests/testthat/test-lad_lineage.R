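test_that("the 10-kb LAD overlap rule is an exact threshold", {
  region <- data.frame(chrom = "chr1", start = 100000, end = 300000)
  lad_9999 <- list(ESC = data.frame(chrom = "chr1", start = 0,
                                    end = 109999))
  lad_10k <- list(ESC = data.frame(chrom = "chr1", start = 0, end = 110000))
  expect_equal(lad_overlap(region, lad_9999)$summary$n_any, 0)
  expect_equal(lad_overlap(region, lad_10k)$summary$n_any, 1)
})

test_that("fragmented LADs within one cell type jointly satisfy the rule", {
  region <- data.frame(chrom = "chr1", start = 100000, end = 300000)
  # two 6-kb fragments: each below threshold, union (book-ended) above
  frags <- list(ESC = data.frame(chrom = "chr1",
                                 start = c(120000, 126000),
                                 end = c(126000, 132000)))
  expect_equal(lad_overlap(region, frags)$summary$n_any, 1)
})

test_that("constitutive/facultative/none statuses follow the definition", {
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 1e6, 2e6), end = c(2e5, 1.2e6, 2.2e6),
                        id = c("all", "one", "none"))
  cover <- function(r) data.frame(chrom = "chr1", start = r[1], end = r[2])
  lads <- list(A = rbind(cover(c(0, 2e5)), cover(c(1e6, 1.2e6))),
               B = cover(c(0, 2e5)), C = cover(c(0, 2e5)),
               D = cover(c(0, 2e5)))
  lc <- lad_overlap(regions, lads)
  expect_equal(lc$records$status, c("CONSTITUTIVE", "FACULTATIVE", "NONE"))
  s <- lc$summary
  expect_equal(s$n_any + s$n_none, s$n_regions)
  expect_equal(s$n_any, s$n_constitutive + s$n_facultative)
  expect_error(lad_overlap(regions, list()), "empty LAD collection")
  expect_error(lad_overlap(regions, list(cover(c(0, 1)))), "labels")
})

test_that("LAD counts are monotone non-increasing in min_overlap", {
  withr::with_seed(77, {
    regions <- rand_intervals(10, list(chr1 = 1e6), max_len = 2e5)
    lads <- list(A = rand_intervals(8, list(chr1 = 1e6), max_len = 3e5),
                 B = rand_intervals(8, list(chr1 = 1e6), max_len = 3e5))
  })
  counts <- vapply(c(1, 5000, 10000, 50000, 100000), function(mo) {
    lad_overlap(regions, lads, min_overlap = mo)$summary$n_any
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("synthetic LAD tracks reproduce the generator truth exactly", {
  cfg <- sim_config(genome = c(chrS = 3e6), n_arrays = 5,
                    array_length = 120000, min_array_gap = 200000,
                    background_density = 0.1, array_density = 0.8,
                    other_class_density = NULL, n_clusters = 2,
                    lad_cover_prob = c(0.8, 0.6, 0.6, 0.3))
  for (seed in c(21, 22, 23)) {
    sim <- simulate_annotation(cfg, seed = seed)
    lc <- lad_overlap(sim$truth$arrays, sim$lads, min_overlap = 10000)
    expect_equal(lc$records$status, sim$truth$arrays$lad_status)
    expect_equal(lc$summary$n_constitutive,
                 sum(sim$truth$arrays$lad_status == "CONSTITUTIVE"))
    expect_equal(lc$summary$n_none,
                 sum(sim$truth$arrays$lad_status == "NONE"))
    # per cell type, the counted regions are exactly the covered arrays
    for (ct in names(sim$lads)) {
      hit <- vapply(seq_len(NROW(sim$truth$arrays)), function(i) {
        intersect_length(sim$lads[[ct]], sim$truth$arrays[i, ]) >= 10000
      }, TRUE)
      expect_setequal(sim$truth$arrays$id[hit],
                      sim$truth$lad_covered_arrays[[ct]])
    }
  }
})

test_that("lineage assignment applies ordered prefix rules", {
  map <- default_lineage_map()
  expect_equal(assign_lineage(c("L1Md_Tf", "Lx2", "L1_Mur3", "L1ME1",
                                "L1MB5", "HAL1"), map),
               c("Mus", "Muridae", "Rodent", "Eutherian", "Eutherian",
                 "unassigned"))
  expect_equal(attr(map, "levels"),
               c("Eutherian", "Rodent", "Muridae", "Mus"))
})

test_that("lineage counts conserve within + outside = genome-wide", {
  withr::with_seed(88, {
    iv <- rand_intervals(400, list(chr1 = 1e6), max_len = 5000)
    nm <- sample(c("L1Md_T", "Lx2", "L1_Mur1", "L1ME1", "B1_Mus1"), 400,
                 replace = TRUE)
    regions <- rand_intervals(6, list(chr1 = 1e6), max_len = 1e5)
  })
  reps <- as_repeats(iv)
  reps$rep_name <- nm
  reps$rep_family <- ifelse(startsWith(nm, "B1"), "B1", "L1")
  reps$rep_class <- ifelse(startsWith(nm, "B1"), "SINE", "LINE")
  tab <- lineage_stratify(reps, regions)
  expect_equal(tab$count_within_arrays + tab$count_outside_arrays,
               tab$count_genomewide)
  expect_equal(sum(tab$count_genomewide) + attr(tab, "unassigned"),
               sum(reps$rep_family == "L1"))
  # no regions -> nothing within
  tab0 <- lineage_stratify(reps, regions[0, ])
  expect_equal(tab0$count_within_arrays, rep(0, 4))
  expect_equal(tab0$count_genomewide, tab$count_genomewide)
  # every element inside one huge region -> within equals genome-wide
  tab1 <- lineage_stratify(reps, data.frame(chrom = "chr1", start = 0,
                                            end = 1e6))
  expect_equal(tab1$count_within_arrays, tab1$count_genomewide)
  # ratios are normalized to the first lineage
  expect_equal(tab$ratio_genomewide,
               tab$count_genomewide / tab$count_genomewide[1])
})

test_that("array membership follows the element midpoint", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  # element straddling the start: midpoint decides
  reps <- as_repeats(data.frame(chrom = rep("chr1", 2),
                                start = c(900, 980), end = c(1150, 1020)))
  # midpoints 1025 (in) and 1000 (in, half-open start is inclusive)
  tab <- lineage_stratify(reps, regions)
  expect_equal(sum(tab$count_within_arrays), 2)
  reps2 <- as_repeats(data.frame(chrom = "chr1", start = 1990, end = 2030))
  # midpoint 2010 falls beyond the half-open end
  tab2 <- lineage_stratify(reps2, regions)
  expect_equal(sum(tab2$count_within_arrays), 0)
})
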