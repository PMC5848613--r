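---
title: "Calling and characterizing dense LINE-1 repeat arrays"
author: "linescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing dense LINE-1 repeat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linescape)
```

## The analysis

LINE-1 (L1) retrotransposons make up a large share of mammalian genomes and
are not uniformly distributed: AT-rich, gene-poor territory accumulates
them, and occasional loci carry *arrays* — stretches of a hundred kilobases
or more in which the majority of bases derive from LINEs. `linescape`
implements the in-silico side of characterizing such arrays from standard
annotation files:

1. **Window scan and array calling** — sliding-window LINE coverage over a
   genome, and merging of high-coverage windows into called array regions.
2. **Genomic context** — classifying each array against a gene annotation
   as intergenic, intragenic, gene-flanking, or within-and-flanking.
3. **Tandem-cluster enrichment** — testing whether arrays contain genes of
   tandemly duplicated families (olfactory `Olfr`, vomeronasal `Vmn`
   receptors) more often than seeded random regions do, with an exact
   binomial tail probability.
4. **Lamina association** — intersecting arrays with lamina-associated
   domain (LAD) tracks from several cell types and classifying them as
   constitutive (all cell types), facultative, or unassociated.
5. **Lineage stratification** — counting L1 elements per amplification
   lineage (Eutherian, Rodent, Muridae, *Mus*) inside versus outside
   arrays, via subfamily-name prefix rules.
6. **Composition and L1 intactness** — per-interval repeat composition and
   a simplified full-length/ORF/poly(A) intactness verdict per element
   sequence.

A seeded synthetic-annotation generator with a recorded truth set stands in
for genome-scale downloads, so every stage is testable against known
ground truth on a laptop.

## Window scan and array calling

Coverage is computed per window on the **union** of the class-filtered
features, so overlapping or doubly annotated fragments count each base
once. Windows of width $W$ start at $0, s, 2s, \dots$ per chromosome and
only windows fully inside the chromosome are emitted: truncated end
windows would mix denominators and inflate variance. The defaults are the
genome-wide screening parameters, $W = 100$ kb, $s = 10$ kb; the
`imprinted` preset ($W = 50$ kb, $d = 0.40$, $L = 50$ kb) is the finer
variant for screening imprinted domains.

A window *qualifies* when its covered fraction strictly exceeds the
density threshold $d$ (default 0.70, i.e. ">70%"); overlapping or
book-ended qualifying windows merge, and the merged span is kept as an
array when it reaches the length threshold $L$ (default 100 kb, with
$\ge$ so that a single qualifying window is a valid call). Two
consequences are worth stating plainly:

* Region boundaries are the union span of qualifying windows and are
  **not** trimmed to repeat edges. A window overhanging a true array edge
  by $\delta$ still qualifies while
  $(W-\delta)p_1 + \delta p_0 > W d$, so with $p_1 = 0.85$,
  $p_0 = 0.20$ the called boundary can overshoot the true edge by up to
  $W(p_1 - d)/(p_1 - p_0) \approx 23$ kb — about two grid steps. Boundary
  accuracy is therefore window-resolution, not base-pair, accuracy; the
  recomputed density over the final span is reported for transparency and
  may legitimately fall below $d$ when merged flanks dilute it.
* Raising $d$ can only remove windows, so calls are monotone in the
  threshold; this is asserted as a property test.

```{r scan-demo}
sim <- simulate_annotation(sim_config(), seed = 7)
p <- scan_params()
regions <- call_arrays(window_scan(sim$repeats, sim$genome, p), p,
                       sim$repeats)
regions[, c("chrom", "start", "end", "length", "density", "n_windows")]
```

## Coordinates and interval arithmetic

All coordinates are 0-based half-open (BED convention); RepeatMasker
`.out` files (1-based inclusive) are converted on read, and features on
chromosomes missing from the genome map are rejected with an error rather
than dropped, so catalog counts cannot silently drift. Interval union,
intersection length and coverage are a vectorized sort-and-scan over
per-chromosome interval lists — coverage is a base-set property, so
book-ended intervals merge. The test suite verifies these primitives
exactly against a per-base boolean-mask oracle on a thousand random
instances.

## The enrichment test

For a gene-family pattern (a regex on gene names), a region is a success
when at least one matching gene overlaps it by $\ge 1$ bp (full
containment is available as an option; the choice matters for genes
straddling array edges). The background success probability is estimated
from `n_random` seeded random regions — lengths cycled from the sorted
observed array lengths — placed with chromosome probability proportional
to the number of valid start positions. The estimate uses a $+0.5/+1$
continuity correction so an empty background cannot produce a zero
estimate, and the p-value is the exact upper tail
$P(X \ge k_{obs})$, $X \sim \mathrm{Bin}(n_{regions}, \hat p)$, computed
by log-gamma summation (enumeration-exact to well below $10^{-12}$).

Because only two families are tested, raw p-values are reported without
multiple-testing correction; nulls are not matched for GC or gene
density.

### Calibration of the null

The generator's null configuration places tandem clusters uniformly
genome-wide, independent of arrays, by density-weighted rejection
sampling (weight `ef` inside arrays, 1 outside; `ef = 1` is exactly
uniform), and draws the realized cluster count from a Poisson law so that
successes of disjoint regions are independent — the sampling model the
binomial test assumes. Two design points deserve a note, because they
were chosen to make the calibration study meaningful rather than
vacuously conservative:

* **Enough regions.** With few regions the exact binomial's achievable
  tail sizes are coarse (at 20 regions the tails nearest 0.05 are 0.021
  and 0.058), so the rejection rate at nominal 0.05 is dominated by
  discreteness. The calibration landscape uses 50 regions.
* **A dense cluster field.** The background probability is estimated from
  the *same* dataset's random regions. If the cluster field is sparse,
  dataset-to-dataset field fluctuations correlate the observed count with
  its own background estimate (we measured a correlation above 0.5 on a
  20-Mb genome with 120 expected clusters), which makes the procedure
  conservative. The calibration landscape therefore uses an 80-Mb
  chromosome with 480 expected clusters, where the field density
  concentrates and the correlation is negligible.

Under this null, the fraction of datasets with $p < 0.05$ sits near
0.04–0.06 across seed banks; under tenfold planted enrichment,
$p < 0.01$ in effectively all datasets. Both studies are rerun from
scratch by the acceptance suite and `scripts/acceptance.R`.

## LAD overlap

Within one cell type, LAD fragments are unioned before measuring overlap,
so adjacent fragments jointly satisfy the minimum-overlap rule — the rule
concerns total lamina contact, not single-fragment geometry. A region
counts as lamina-associated in a cell type when the intersection reaches
`min_overlap` (default 10 kb, an exact threshold: 9,999 bp does not
count); `CONSTITUTIVE` requires every assayed cell type, `FACULTATIVE` at
least one.

## Lineage stratification

Elements are assigned to lineages by ordered subfamily-name prefix rules
(`L1Md_*` → *Mus*, `Lx*` → Muridae, `L1_Mur*` → Rodent,
`L1ME*`/`L1MB*` → Eutherian by default; the mapping ships as an editable
TSV for other genomes). An element is *within* an array when its midpoint
falls inside a called region — midpoints prevent double counting of
boundary-straddling elements — and unmatched names are reported as
`unassigned` rather than silently folded into a lineage. Within + outside
= genome-wide holds exactly on any input.

## L1 intactness

Full-length L1 databases apply family-specific criteria that are not
reproduced here; instead a transparent, configurable classifier applies
four checks per element: length at least `full_length_fraction` of the
expected element length; an ORF1 of `orf1_min_aa` codons starting within
the 5' search window; an ORF2 of `orf2_min_aa` codons downstream of the
chosen ORF1 (or of the window when no ORF1 qualifies); and an `AATAAA`
poly(A) signal within the final `polya_window` bases. ORF scanning covers
the three forward frames only (inputs are sense-oriented extractions);
codons containing N terminate an ORF as "ambiguous"; a frameshift is
detected only through its consequence — the loss of a qualifying ORF —
because alignment-based defect calling is out of scope. Defaults sit near
the canonical mouse L1 ORF sizes (ORF1 ~375 aa, ORF2 ~1275 aa) with
deliberately permissive margins (300/1200 aa).

## The synthetic generator

`simulate_annotation()` emits the formats the readers consume
(chrom.sizes, UCSC-rmsk-layout repeats, BED genes and per-cell-type LAD
tracks) plus a truth set, deterministically per (configuration, seed).
Design choices:

* **Repeats as a marked point process.** Element starts are uniform
  within a stratum (planted array or background gap), lengths geometric
  (mean 600 bp), overlaps allowed — union coverage is the controlled
  quantity, matching how real RepeatMasker tracks behave. Placement stops
  when the stratum reaches its target coverage, so realized coverage
  lands within about half an element length of the target (recorded in
  the truth set; audited at ±0.03).
* **Defaults are the validation regime**: one 5-Mb chromosome, background
  LINE coverage 0.20, ten planted 150-kb arrays at 0.85, separated by at
  least 200 kb so that distinct arrays remain resolvable by a 100-kb
  window scan. The within-array lineage mixture defaults to the skew
  observed in real mouse arrays (Eutherian : Rodent : Muridae : *Mus*
  near 372 : 747 : 2004 : 2800) and the background to the genome-wide
  near-1:1:1:1 ratio.
* **LAD truth stays identifiable.** Planted-array LADs may extend up to
  40 kb beyond the array; background LADs keep a 50-kb buffer away from
  every planted array. Since a called region can overhang its array by at
  most ~25 kb (see above), the truth LAD status of a planted array is
  exactly the status of its called region.
* **Sequences** (`simulate_l1_fasta()`) derive from a designed consensus:
  codon-random stop-free ORFs with guard stop codons immediately 5' of
  each ATG (so an injected premature stop cannot be rescued by upstream
  in-frame extension), ORF2 starting just after the ORF1 search window
  (so destroying ORF1 does not collaterally invalidate ORF2 under the
  fallback rule), and exactly one poly(A) signal inside the 3' window.
  Injected stops are positioned so that neither fragment still qualifies;
  frameshifts are placed early in ORF2 so the in-frame fragment stays far
  below threshold.

What the generator does **not** emulate: real sequence content for
annotated repeats (annotations only, except the L1 FASTA path), subfamily
divergence structure beyond a per-lineage milliDiv range, GC/gene-density
covariation, and fragmented rmsk element IDs (each line is an independent
feature). Passing tests therefore demonstrate algorithmic correctness
under a controlled landscape, not robustness to every artifact of real
annotation tracks — though the readers accept real UCSC rmsk/BED inputs,
so genome-scale runs are possible where the downloads are available.

## Numerical and degenerate-input choices

* Strict `>` for window qualification, `>=` for the length filter.
* Zero-length windows and intervals are errors for coverage questions;
  zero-length BED intervals are accepted on read (they cover no bases).
* `binomial_pvalue(0, n, p) = 1` by construction; `p = 0` or `1` are
  handled as exact limits.
* Random placement is reproducible bitwise per seed; the generator state
  is saved and restored around every seeded operation, so library calls
  never touch the caller's RNG stream.
* Chromosome order in sorted outputs is C-locale radix order, making
  results independent of input line order and of the session locale.

## Problem sizes in the validation studies

The test and acceptance studies run at deliberately desk-scale sizes: a
thousand random interval instances against the per-base oracle; 200
random annotations for the window oracle; 20 replicate landscapes for
planted-array recovery; 200 null and 100 enriched datasets for the
enrichment calibration; one ~10,000-element landscape for lineage mixture
recovery; 100 elements per defect class for intactness. The full suite
and the acceptance script each complete in a few minutes on one CPU.

## Known limitations

* Boundary accuracy of called arrays is limited to window resolution, as
  derived above; per-base array edges would require a trimming rule this
  implementation deliberately does not define.
* The context label table is one deterministic reading of the four
  categories; the mapping is centralized in a single internal function so
  an alternative reading is a one-line change.
* Only forward-strand ORFs are scanned, and intactness thresholds are
  heuristics, not a reimplementation of curated full-length L1 databases.
* Enrichment nulls are not matched for GC content, gene density, or
  repeat landscape.
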