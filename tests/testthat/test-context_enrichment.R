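mk_genes <- function(starts, ends, names = NULL) {
  data.frame(chrom = rep("chr1", length(starts)), start = starts, end = ends,
             name = names %||% sprintf("g%d", seq_along(starts)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("context labels follow the relation table exhaustively", {
  region <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  enclosing <- c(500, 2500)     # region inside gene      -> CONTAINED
  contained <- c(1200, 1400)    # gene inside region      -> CONTAINS
  partial <- c(1800, 2600)      # straddles the edge      -> PARTIAL
  cases <- list(
    list(genes = NULL, label = "INTERGENIC"),
    list(genes = mk_genes(enclosing[1], enclosing[2]), label = "INTRAGENIC"),
    list(genes = mk_genes(partial[1], partial[2]), label = "GENE_FLANKING"),
    list(genes = mk_genes(contained[1], contained[2]),
         label = "WITHIN_AND_FLANKING"),
    list(genes = mk_genes(c(contained[1], partial[1]),
                          c(contained[2], partial[2])),
         label = "WITHIN_AND_FLANKING"),
    list(genes = mk_genes(c(enclosing[1], partial[1]),
                          c(enclosing[2], partial[2])),
         label = "WITHIN_AND_FLANKING"),
    list(genes = mk_genes(c(enclosing[1], contained[1]),
                          c(enclosing[2], contained[2])),
         label = "WITHIN_AND_FLANKING"),
    # identical coordinates: the region holds a whole gene body
    list(genes = mk_genes(1000, 2000), label = "WITHIN_AND_FLANKING"),
    # gene outside the region entirely
    list(genes = mk_genes(3000, 4000), label = "INTERGENIC"),
    # book-ended gene (half-open: no shared base)
    list(genes = mk_genes(2000, 2400), label = "INTERGENIC")
  )
  for (cs in cases) {
    rep <- classify_context(region,
                            cs$genes %||% mk_genes(numeric(0), numeric(0)))
    expect_equal(rep$regions$context, cs$label)
    expect_equal(sum(rep$summary), 1)       # labels partition the regions
  }
})

test_that("context summary counts partition regions and count gene content", {
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 5000, 10000, 15000),
                        end = c(1000, 6000, 11000, 16000))
  genes <- mk_genes(c(100, 4000, 15500), c(200, 7000, 15800),
                    c("inA", "overB", "inD"))
  rep <- classify_context(regions, genes)
  expect_equal(unname(sum(rep$summary)), 4)
  expect_equal(unname(rep$summary["INTERGENIC"]), 1)
  expect_equal(unname(rep$summary["INTRAGENIC"]), 1)
  expect_equal(unname(rep$summary["WITHIN_AND_FLANKING"]), 2)
  # the enclosing-gene region does not itself contain a gene
  expect_equal(rep$contains_genes_count, 2)
  expect_equal(rep$regions$contained_genes[1], "inA")
})

test_that("binomial upper tail is exact against pmf enumeration", {
  expect_equal(binomial_pvalue(0, 10, 0.3), 1.0)
  expect_equal(binomial_pvalue(2, 2, 0.5), 0.25)
  expect_equal(binomial_pvalue(7, 10, 0.2),
               oracle_binom_tail(7, 10, 0.2), tolerance = 1e-14)
  for (n in c(1, 5, 12)) {
    for (k in 0:n) {
      for (p in c(0.05, 0.37, 0.5, 0.91)) {
        expect_lt(abs(binomial_pvalue(k, n, p) - oracle_binom_tail(k, n, p)),
                  1e-12)
      }
    }
  }
  # monotone: non-increasing in k, non-decreasing in p
  ks <- vapply(0:10, binomial_pvalue, 0, n = 10, p = 0.4)
  expect_true(all(diff(ks) <= 0))
  ps <- vapply(seq(0.05, 0.95, 0.1), function(p)
    binomial_pvalue(4, 10, p), 0)
  expect_true(all(diff(ps) >= 0))
  # edge handling and input validation
  expect_equal(binomial_pvalue(0, 5, 0), 1)
  expect_equal(binomial_pvalue(3, 5, 0), 0)
  expect_equal(binomial_pvalue(5, 5, 1), 1)
  expect_error(binomial_pvalue(6, 5, 0.5), "exceed")
  expect_error(binomial_pvalue(2, 5, 1.5), "\\[0, 1\\]")
})

test_that("cluster enrichment is seeded, order-invariant and validates input", {
  gm <- genome_map(c(chr1 = 1e6))
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 2e5, 4e5, 6e5),
                        end = c(1e5, 3e5, 5e5, 7e5))
  genes <- mk_genes(c(5e4, 2.5e5, 9e5, 9.2e5), c(5.2e4, 2.6e5, 9.1e5, 9.3e5),
                    c("Olfr1", "Olfr2", "Olfr3", "GeneX"))
  r1 <- cluster_enrichment(regions, genes, "^Olfr", gm, n_random = 100,
                           seed = 7)
  expect_equal(r1$k_observed, 2)
  expect_equal(r1$n_regions, 4)
  expect_gt(r1$p_hat, 0)
  expect_lt(r1$p_hat, 1)
  r2 <- cluster_enrichment(regions, genes, "^Olfr", gm, n_random = 100,
                           seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  # shuffled regions and genes give the identical p-value
  r3 <- cluster_enrichment(regions[c(3, 1, 4, 2), ], genes[c(4, 2, 1, 3), ],
                           "^Olfr", gm, n_random = 100, seed = 7)
  expect_identical(r1$p_value, r3$p_value)
  expect_error(cluster_enrichment(regions, genes, "^Vmn", gm,
                                  n_random = 100, seed = 1),
               "matches no gene")
})

test_that("zero observed successes give p = 1 regardless of background", {
  gm <- genome_map(c(chr1 = 1e6))
  regions <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  genes <- mk_genes(9e5, 9.1e5, "Olfr1")
  r <- cluster_enrichment(regions, genes, "^Olfr", gm, n_random = 100,
                          seed = 3)
  expect_equal(r$k_observed, 0)
  expect_equal(r$p_value, 1)
})

test_that("containment mode is stricter than any-overlap mode", {
  gm <- genome_map(c(chr1 = 1e6))
  regions <- data.frame(chrom = "chr1", start = 1e5, end = 2e5)
  # gene straddles the region edge: overlaps but is not contained
  genes <- mk_genes(1.95e5, 2.05e5, "Olfr1")
  any_mode <- cluster_enrichment(regions, genes, "^Olfr", gm,
                                 n_random = 100, seed = 5)
  within_mode <- cluster_enrichment(regions, genes, "^Olfr", gm,
                                    n_random = 100, seed = 5,
                                    overlap_mode = "contained")
  expect_equal(any_mode$k_observed, 1)
  expect_equal(within_mode$k_observed, 0)
})
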