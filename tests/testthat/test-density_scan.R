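toy_genome <- function() genome_map(c(chrA = 100000, chrB = 60000))

toy_params <- function(min_density = 0.5) {
  scan_params(window = 10000, step = 2000, min_density = min_density,
              min_length = 10000)
}

test_that("scan parameter presets and invariants hold", {
  p <- scan_params()
  expect_equal(p$window, 100000)
  expect_equal(p$step, 10000)
  expect_equal(p$min_density, 0.70)
  expect_equal(p$min_length, 100000)
  p <- scan_params("imprinted")
  expect_equal(p$window, 50000)
  expect_equal(p$min_density, 0.40)
  expect_equal(p$min_length, 50000)
  expect_error(scan_params(step = 0), "step")
  expect_error(scan_params(step = 2e5), "step")
  expect_error(scan_params(min_length = 5e4), "min_length")
})

test_that("window scan emits full windows with union-based fractions", {
  gm <- genome_map(c(chrT = 300))
  reps <- as_repeats(data.frame(chrom = "chrT", start = 0, end = 300))
  p <- scan_params(window = 100, step = 100, min_density = 0.5,
                   min_length = 100)
  w <- window_scan(reps, gm, p)
  expect_equal(NROW(w), 3)
  expect_equal(w$fraction, rep(1, 3))

  # no LINE features -> all zero (SINEs do not count)
  reps2 <- as_repeats(data.frame(chrom = "chrT", start = 0, end = 300),
                      rep_class = "SINE")
  expect_equal(window_scan(reps2, gm, p)$fraction, rep(0, 3))

  # chromosome shorter than W yields no windows; partial end windows drop
  gm2 <- genome_map(c(chrT = 350, chrU = 80))
  w2 <- window_scan(reps, gm2, p)
  expect_equal(unique(w2$chrom), "chrT")
  expect_equal(max(w2$end), 300)
})

test_that("window fractions match per-base counting on random annotations", {
  gm <- toy_genome()
  chromlens <- as.list(as.numeric(gm))
  names(chromlens) <- names(gm)
  p <- toy_params()
  withr::with_seed(202, {
    for (rep in 1:30) {
      iv <- rand_intervals(200, chromlens, max_len = 800)
      reps <- as_repeats(iv)
      w <- window_scan(reps, gm, p)
      masks <- mask_of(iv, chromlens)
      oracle <- vapply(seq_len(NROW(w)), function(i) {
        mean(masks[[w$chrom[i]]][(w$start[i] + 1):w$end[i]])
      }, 0)
      expect_equal(w$fraction, oracle)
    }
  })
})

test_that("array calling merges qualifying windows and keeps span >= L", {
  # qualifying windows at starts 0..50k (W = 100k) -> one region 0-150k
  w <- data.frame(chrom = "chr1", start = seq(0, 50000, 10000),
                  end = seq(0, 50000, 10000) + 100000,
                  covered_bp = 80000, fraction = 0.8)
  p <- scan_params()
  regs <- call_arrays(w, p)
  expect_equal(NROW(regs), 1)
  expect_equal(regs$start, 0)
  expect_equal(regs$end, 150000)
  expect_equal(regs$n_windows, 6)
  expect_true(is.na(regs$density))

  # strict '>' qualification: fraction exactly at threshold does not count
  w$fraction <- p$min_density
  expect_equal(NROW(call_arrays(w, p)), 0)
})

test_that("tiling scan (s = W) recovers total union coverage exactly", {
  gm <- genome_map(c(chrA = 100000))
  withr::with_seed(33, {
    iv <- rand_intervals(120, list(chrA = 100000), max_len = 900)
  })
  reps <- as_repeats(iv)
  p <- scan_params(window = 10000, step = 10000, min_density = 0.5,
                   min_length = 10000)
  w <- window_scan(reps, gm, p)
  expect_equal(sum(w$covered_bp),
               total_length(union_intervals(iv)))
})

test_that("raising min_density never adds regions or extends boundaries", {
  gm <- toy_genome()
  withr::with_seed(44, {
    iv <- rand_intervals(400, list(chrA = 100000, chrB = 60000),
                         max_len = 2000)
  })
  reps <- as_repeats(iv)
  w <- window_scan(reps, gm, toy_params())
  lo <- call_arrays(w, toy_params(min_density = 0.3))
  hi <- call_arrays(w, toy_params(min_density = 0.45))
  for (i in seq_len(NROW(hi))) {
    host <- lo[lo$chrom == hi$chrom[i] & lo$start <= hi$start[i] &
                 lo$end >= hi$end[i], ]
    expect_equal(NROW(host), 1)   # every high-threshold region nests in one
  }
  expect_lte(NROW(hi), NROW(lo))
})

test_that("recomputed region density matches the brute-force recount", {
  gm <- toy_genome()
  chromlens <- list(chrA = 100000, chrB = 60000)
  withr::with_seed(55, {
    iv <- rand_intervals(500, chromlens, max_len = 1500)
  })
  reps <- as_repeats(iv)
  p <- toy_params(min_density = 0.4)
  regs <- call_arrays(window_scan(reps, gm, p), p, reps)
  masks <- mask_of(iv, chromlens)
  for (i in seq_len(NROW(regs))) {
    expect_equal(regs$density[i],
                 mean(masks[[regs$chrom[i]]][(regs$start[i] + 1):
                                               regs$end[i]]))
  }
  expect_gt(NROW(regs), 0)
})

test_that("region composition reports per-class and total fractions", {
  reps <- rbind(
    as_repeats(data.frame(chrom = "chrT", start = 0, end = 500)),
    as_repeats(data.frame(chrom = "chrT", start = 500, end = 750),
               rep_class = "SINE", rep_family = "B1", rep_name = "B1_Mus1"))
  comp <- region_composition(list(chrom = "chrT", start = 0, end = 1000),
                             reps)
  expect_equal(comp$fraction[comp$rep_class == "LINE"], 0.5)
  expect_equal(comp$fraction[comp$rep_class == "SINE"], 0.25)
  expect_equal(attr(comp, "total_fraction"), 0.75)

  # full coverage by one class
  one <- as_repeats(data.frame(chrom = "chrT", start = 0, end = 100))
  comp1 <- region_composition(list(chrom = "chrT", start = 0, end = 100), one)
  expect_equal(comp1$fraction, 1)
  expect_equal(attr(comp1, "total_fraction"), 1)

  expect_error(region_composition(list(chrom = "chrT", start = 5, end = 5),
                                  reps), "zero-length")
})

test_that("composition agrees with per-base class masks on random data", {
  chromlens <- list(chrA = 20000)
  withr::with_seed(66, {
    classes <- c("LINE", "SINE", "LTR", "DNA")
    iv <- rand_intervals(150, chromlens, max_len = 600)
    cls <- sample(classes, 150, replace = TRUE)
  })
  reps <- as_repeats(iv)
  reps$rep_class <- cls
  win <- list(chrom = "chrA", start = 3000, end = 15000)
  comp <- region_composition(win, reps)
  for (cl in unique(cls)) {
    m <- mask_of(iv[cls == cl, ], chromlens)[["chrA"]]
    expect_equal(comp$fraction[comp$rep_class == cl],
                 mean(m[(win$start + 1):win$end]))
  }
  m_all <- mask_of(iv, chromlens)[["chrA"]]
  expect_equal(attr(comp, "total_fraction"),
               mean(m_all[(win$start + 1):win$end]))
  expect_gte(attr(comp, "total_fraction"), max(comp$fraction))
})
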