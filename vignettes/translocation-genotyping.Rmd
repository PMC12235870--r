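---
title: "Methods: depth-of-coverage and breakpoint-PCR genotyping of the Cs translocations"
author: "cstyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-of-coverage and breakpoint-PCR genotyping of the Cs translocations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstyper)
```

## The alleles and their copy-number signature

The Cs29 allele is a translocation that duplicates a ~500 kbp segment of
chromosome 6 — containing the *KIT* gene — onto chromosome 29. The Cs6
allele derives from the Cs29 configuration by a further rearrangement that
moves material back to chromosome 6; its carriers show elevated copy
number over both the chromosome-6 *KIT* segment and a chromosome-29
segment. `cstyper` models an allele purely by its copy-number
consequences: a list of gained regions, each contributing `copies_added`
extra copies per carried allele. The wild-type allele contributes nothing.

With a diploid baseline of 2 copies everywhere, a genotype's expected
copy number over a region is `2 + sum(count_a * gain_a)` and its expected
standardized depth-of-coverage ratio is that number divided by 2 —
1.0 / 1.5 / 2.0 for 2 / 3 / 4 copies. These constants are not free
parameters; they follow from the allele model, and the package exposes
them through `expected_depth_ratio()`.

Region coordinates are configuration, not constants. Published breakpoint
coordinates for these alleles predate the current cattle assembly and are
obtained by coordinate lift-over, so the shipped
`inst/extdata/allele_models.yaml` carries clearly-labelled placeholder
coordinates that a user must replace before scoring real alignments. All
coordinates are 0-based half-open (BED convention) internally, with
1-based inclusive strings for display.

## Depth genotyping

The pipeline follows the windowed-coverage approach: depth records
(bedGraph or per-window TSV) are binned into fixed windows (default
10 kbp) as length-weighted means, then standardized by the median depth
over all non-missing windows. Key choices:

* **Genome-wide median.** Standardization divides by the median over the
  whole track. A region-local median can be obtained by subsetting the
  track before `standardize()`; the genome-wide default is preferred
  because the duplicated regions themselves are a negligible fraction of
  a real genome and cannot bias a genome-wide median. (This is also why
  the simulator's background must dominate its tracks; see below.)
* **Median region summary.** The observed copy ratio of a region is the
  *median* standardized ratio of the windows fully inside it. The median
  resists outlier windows; excluding boundary-straddling windows avoids
  diluting the signal with windows that only partially overlap the
  duplicated segment.
* **Missing windows** (no coverage records) are excluded from both the
  median and the region summary rather than treated as zero: absence of
  records usually means unmappable sequence, not zero copy number.

The genotype caller replaces visual comparison against 1.5x/2x reference
lines with an explicit rule: every genotype in the enumerated six-genotype
space is scored by the sum of squared differences between observed and
expected ratios over the scored regions, and the arg-min wins. In a
single-region problem this is exactly a nearest-expected-ratio classifier
with thresholds at the class midpoints 1.25 and 1.75 (verified against a
brute-force classifier in the test suite). Two tunable guards flag a call
as `"ambiguous"` rather than `"pass"`:

* best-vs-second score difference below `margin` (default 0.01);
* any observed ratio within `midpoint_tol` (default 0.05) of a midpoint
  between two expected ratio classes.

The defaults are deliberately conservative. With 150 windows per region
the median's sampling error at 26X is below 0.03, so ambiguity flags are
rare at study-like coverage and appear, together with miscalls, only when
the evidence becomes genuinely thin (very low coverage or few windows) —
which is exactly when a human reviewer should look at the track.

## What the simulator emulates — and what it does not

`simulate_depth_track()` draws per-window read counts with mean
`mean_depth * expected_ratio`: Poisson by default (`dispersion = 0`), or
negative-binomial with variance `mu + dispersion * mu^2` for robustness
checks. Defaults describe a study-like setting: 10 kbp windows and a mean
depth of 26, a typical average mapped coverage for a whole-genome-sequenced
cohort of this kind.

The background (diploid, pseudo-chromosome `"bg"`) has 5000 windows by
default. The background must dominate the simulated track: in a real
genome the few Mbp of duplicated sequence is negligible against ~2.7 Gbp,
so the genome-wide median is anchored by diploid sequence. A small
simulated background (say 500 windows against 300 elevated ones) would
push the median to the background's upper quantiles and bias every
standardized ratio downward — an artifact of the miniature genome, not a
property of the method.

Not simulated: GC and mappability bias, reference errors, alignment
artifacts, and breakpoint-adjacent partial windows. Median standardization
removes global scale effects, but regional bias in real data can shift
observed ratios in ways the simulation never exercises — passing
simulation-based recovery tests therefore demonstrates the decision rule's
statistical behaviour, not robustness to real-data bias. The count model
is per-window counts at the coverage value, which makes window-level noise
comparable to what per-window depth shows in practice once mappability
variation is included; it also means simulated standardized ratios are
discrete (multiples of one over the median), which matters only at very
low simulated coverage.

`simulate_haplotype()` builds uniform-composition random backgrounds and
plants primer footprints exactly (an option injects mismatches to exercise
the scanner). `simulate_population()` draws two alleles per animal i.i.d.
from the configured frequencies — Hardy–Weinberg equilibrium — and masks
dominant markers to presence/absence without altering the underlying
counts. All generators are bit-reproducible under a fixed seed.

## In-silico PCR

Primer-site scanning matches IUPAC primers against both strands with a
mismatch budget, but always requires the 3'-terminal base to match
exactly: polymerase extension needs a paired 3' end, so a terminal
mismatch would not amplify regardless of overall similarity. Amplicons are
every convergent (plus-strand site upstream of a minus-strand site,
footprints non-overlapping) combination with product length — measured 5'
end to 5' end, inclusive of both footprints, the convention in which assay
product sizes are quoted — up to `max_product` (default 2000 bp).

The real breakpoint primer sequences are published elsewhere; the module
is sequence-generic and ships synthetic fixture primers and templates
(`cs_demo_primers()`, `cs_fixture_templates()`) whose products reproduce
the assay's marker sizes of 318 bp (Cs29 junction), 394 bp (wild-type
chromosome 29) and 525 bp (Cs6 junction). The fixture encodes one
substantive modelling decision: the Cs6 template yields *both* the 394 bp
wild-type-class product and the 525 bp junction product, while the Cs29
template yields only 318 bp. This is the only configuration consistent
with the assay's observed semantics — it makes Cs6/wt and Cs6/Cs6 produce
identical band patterns (the dominant-marker limitation) while keeping
the Cs29 dosage decodable from the 318/394 pair, and it decodes the
three-band pattern {318, 394, 525} as a Cs29 heterozygote carrying Cs6.

Band decoding assigns each observed size to the nearest marker class
within a relative tolerance (default ±3%, typical electrophoretic sizing
error; classes must be separated by more than twice the tolerance). A
pattern with neither a Cs29-class nor a wild-type-class band is reported
as a failed reaction, not a genotype.

## Exact cohort statistics

* **Clopper–Pearson intervals** are computed by inverting the equal-tailed
  binomial test via the incomplete-beta representation (`qbeta`), exact to
  floating-point precision; the test suite cross-checks against the
  independent inversion in `stats::binom.test`. Codominant markers are
  estimated on the gametic scale (2 trials per animal), dominant markers
  on the animal scale.
* **Fisher's exact test** enumerates all tables with the observed margins
  and sums the probabilities of tables no more probable than the observed
  one (relative tie tolerance 1e-7 to absorb floating-point ties) — the
  probability-mass two-sided convention. Enumeration is capped
  (default 2e6 tables) with an error advising Monte-Carlo approximation
  beyond it. An independent brute-force enumerator and
  `stats::fisher.test` serve as oracles in the tests.
* **Cohort comparison** reports per-cohort estimates, the Fisher p on the
  2 x c genotype table, and whether the CIs overlap. Which genotype
  classes enter the table is an explicit option (`"full"` or carrier
  collapse to 2 x 2), since either choice is defensible for comparing
  genotype frequencies between sampling periods.
* A Hardy–Weinberg-based allele-frequency estimator for dominant markers
  (`q = 1 - sqrt(1 - f_positive)`) is provided but separated from the
  primary reporting: it adds an equilibrium assumption that presence
  frequencies do not need.

Report display rounds half away from zero to two decimals (the convention
of frequency tables in this literature); full precision is retained in
the returned objects.

## Problem sizes and determinism

The test suite works at desk scale by design: depth-caller recovery uses
200 simulated animals (six genotypes cycled) at 26X with two 1.5 Mbp
regions of 150 windows each over a 5000-window background; Fisher oracle
equivalence uses 500 random 2x2/2x3 tables with totals up to 40; interval
coverage uses 2000 binomial draws at each of nine (n, p) combinations.
All stochastic tests fix their seeds, so they are deterministic
re-runs, and every simulation function takes an explicit seed.

## Limitations

* Depth genotyping assumes the configured regions really are the gained
  segments; wrong coordinates degrade the observed ratios silently (the
  ambiguity flag is the only guard).
* The caller assumes exactly the enumerated genotype space; a novel allele
  with a different copy-number profile would be forced onto the nearest
  enumerated genotype (though typically with a poor fit score).
* The PCR module models annealing by sequence identity with a 3'-exact
  rule only — no melting temperature, secondary structure, or competition
  effects — so it validates primer placement and product sizes, not assay
  chemistry.
* Cs6 dosage is unrecoverable from the multiplex by construction; any
  Cs6 allele-frequency statement requires the HWE estimator and its
  assumptions.
* Re-analysis of the real sequenced cohort requires the public sequence
  archive and alignment upstream of this package; the package starts at
  depth tracks.
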