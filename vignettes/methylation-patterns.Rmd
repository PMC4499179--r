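---
title: "Methylation co-occurrence patterns from bisulfite amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation co-occurrence patterns from bisulfite amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcooc)
```

## Scope and model

`methcooc` analyses targeted deep bisulfite amplicon sequencing: short reads
(~70–80 bp) from small, known regions (~100–150 bp) at depths where the
joint methylation state of all CpG sites on single molecules — the
*co-occurrence pattern* or epiallele — can be measured reliably. The package
assumes a directional library (original-top and original-bottom bisulfite
strands; the complementary-to-converted strands can be enabled with a flag),
gap-free alignments (amplicon reads of a known template rarely need indels,
and the mapper refuses them by design), and CpG-context methylation only:
the conversion-rate QC treats every non-CpG cytosine as unmethylated, so
tissues with substantial CHH/CHG methylation would need a different QC
metric.

### Mapping

Reads are compared to each region in converted space (read and reference
both C→T for top-strand modes, G→A for bottom-strand modes) at every offset,
a full scan being entirely adequate at amplicon scale. A hit must satisfy
two budgets counted in converted space: at most `max_mismatches` (default 2)
overall and at most `seed_mismatches` (default 3) within the first
`seed_length` (default 28) sequenced bases. The unique best hit wins; any
tie across offsets, regions or strands discards the read as ambiguous.
Discarding rather than picking randomly keeps the pipeline deterministic and
makes "uniquely mapped" counts meaningful. Base qualities are parsed and
validated against the declared encoding (phred33 default; phred64, solexa,
solexa1.3 accepted) but never used in scoring: scoring by quality would make
results depend on instrument calibration in ways that cannot be specified
precisely, whereas the ambiguity-plus-budget rule is exactly reproducible.
The 28 bp seed is a conventional short-read seed length; with 70 bp reads
the seed rule only bites when mismatches cluster early in the read.

### Methylation calling and QC

Top-strand reads are read at the CpG cytosine (C = methylated,
T = unmethylated), bottom-strand reads at the CpG guanine in forward
coordinates (G = methylated, A = unmethylated); both project onto the
forward-strand CpG coordinate, so strands are interchangeable downstream. An
unexpected base at a CpG yields an AMBIGUOUS call: such a read is excluded
from pattern analysis for windows containing that site (the base is likelier
a variant or error than a methylation state) but still feeds the mutation
pileup, where it is evidence.

Two per-read QC metrics gate the analysis, both with inclusive thresholds
(a read sitting exactly on a threshold passes, reading "rate 0.95" as the
minimum acceptable value):

* **Bisulfite conversion rate** (default minimum 0.95): the fraction of
  covered non-CpG cytosines of the read's strand observed converted. A read
  covering no such position passes with rate 1 — there is no evidence of
  failure, and discarding would bias against cytosine-poor windows. The
  denominator is per-read, matching per-read filtering semantics.
* **Sequence identity** (default minimum 0.9): bisulfite-compatible matches
  over the full read length. The denominator is a design choice (the
  alternative — aligned, non-bisulfite positions only — is defensible);
  full-read length was chosen because it penalises Ns and clipped garbage
  that position-restricted denominators hide.

### Window, patterns and the significance test

The analysis window defaults to 70 bp starting at the region's first CpG
site; only CpGs with both bases inside the window count, and only reads
covering *all* window CpGs with definite calls enter pattern generation
(partial reads would make supports incomparable). Reads sharing a signature
form a pattern with support \(n_p\) and fraction \(\hat p = n_p / n\). Each
pattern is tested one-sided against the baseline \(p_0\), defined as one
over the number of observed patterns — deliberately not \(1/2^k\), which
ignores the dependence of neighbouring CpGs and the finite read count:

\[ Z = \frac{\hat p - p_0}{\sqrt{\hat p (1 - \hat p) / n}} \]

The standard deviation is estimated from the observed \(\hat p\), not from
\(p_0\); this is the method's definition and is implemented exactly as
stated, although a textbook one-sample proportion test would use \(p_0\) in
the denominator. The practical consequence is a mildly anti-conservative
test for patterns with \(\hat p\) near 0 or 1; the null-calibration check in
the test suite (uniform signatures, k = 3, n = 2000, 500 replicates) bounds
the realised per-pattern flag rate at α = 0.05 to ≤ 0.08, which it meets
comfortably (≈ 0.04 in practice).

Numerical edge cases are fixed as follows. Unanimity (\(\hat p = 1\), zero
denominator) is maximally significant (Z = ∞, p = 0) when alternatives were
observed possible (\(p_0 < 1\)), and non-significant (Z = 0, p = 1) when the
pattern is the only one observed (\(p_0 = 1\)): a pattern cannot be
significant against itself. Significant patterns sort by descending Z
(equivalent to ascending p-value, as the map is monotone), with ties broken
by descending support and then lexicographic signature — invented
tie-breaks, chosen purely for deterministic output. No multiple-testing
correction is applied by default (the plain 0.05 threshold is the method's
exploratory convention); `significant_patterns(..., bonferroni = TRUE)`
divides α by the number of observed patterns for users who want control.

Pairwise CpG dependence uses the Pearson χ² statistic with 1 df and no
continuity correction on the 2×2 table aggregated from pattern supports. A
zero margin means one site is uniformly methylated or unmethylated and
carries no dependence information; the statistic is then defined as 0 with
p = 1 rather than NaN.

### Mutations and allele-specific methylation

Allele counting excludes conversion-confounded comparisons — top-strand
reads at reference-C positions and bottom-strand reads at reference-G
positions — because there a C/T or G/A difference is methylation, not
genotype. Without this exclusion, bisulfite conversion itself would be
called as a C→T "mutation" at every unmethylated cytosine. The consequence
is that a variant at a CpG position is callable only from the non-confounded
strand, which is also how a real G→A polymorphism at a CpG guanine presents.
A mutation is called where the most frequent non-reference base reaches the
fraction threshold (default 0.2) among counted reads, subject to a coverage
floor of 10 reads (an invented guard against thin-position noise; a flag).
The fraction denominator is the position's counted covering reads, not all
reads — the natural choice when coverage varies across the amplicon.

ASM screening splits window-covering reads by allele at the called mutation
and compares per-site methylation levels banded into LOW (≤ 0.20), HIGH
(≥ 0.80) and INTERMEDIATE. A candidate needs at least one site with the two
groups in different bands *and* a level difference strictly greater than
0.20 — strict, in contrast to the inclusive band boundaries, following the
wording of the rule ("larger than") as opposed to the band definitions
("at least"/"at most"). Both allele groups must contain at least 10 reads
(another invented floor, flagged); below it the result is reported as
insufficient data rather than as a negative call.

## The simulator: what it emulates and what it does not

`simulate_reads()` emulates the study conditions the package is designed
for: a ~127 bp amplicon with evenly spaced CpGs, 70 bp reads whose offsets
always cover the window CpGs, a planted epiallele mixture, both bisulfite
strands (bottom-strand reads emitted reverse-complemented, as sequenced),
per-base conversion failure (default 0.01, i.e. a 99% conversion chemistry),
per-base substitution error (default 0.005, typical of filtered short-read
data), optional per-site methylation flip noise, and an optional variant
allele whose frequency and per-allele epiallele mixes are configurable. The
default depth of 2000 reads is far below real amplicon depths (tens of
thousands); pattern-fraction standard errors scale as \(1/\sqrt n\), so
conclusions at 2000 reads transfer conservatively to deeper data. All
randomness is seeded and the seed is recorded in the FASTQ comment field.

It does **not** model PCR duplicates or amplification bias (real epiallele
fractions can be distorted by PCR in ways no within-sample statistic can
detect), indel sequencing errors (the aligner is gap-free by design),
quality-score degradation along the read, or chimeric reads. Passing tests
therefore demonstrate correctness of the computation under the stated error
model, not robustness to PCR artefacts — on real data the pattern fractions
inherit whatever quantitative bias the amplification introduced.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run, among others: 1000-case
random checks of the Z statistic against direct evaluation (tolerance
1e-12); 200 random windows against a brute-force signature tally; a
500-replicate null calibration at n = 2000; planted-mixture recovery
(0.6/0.3/0.1, 1% flip noise) at n = 10,000 within ±0.03; aligner recovery of
1000 reads with ≤ 2 planted substitutions (≥ 99%) plus exact agreement with
a brute-force all-offset oracle on 100 random cases; conversion-failure
recovery (planted 0.05) at n = 10,000 within three standard errors; and
100-seed ASM detection (allele-linked 0.9 vs 0.1 methylation, variant
frequency 0.5, n = 2000, 1% error) against a 100-seed unlinked control.
These sizes keep the full suite under two minutes on a single core while
leaving the stochastic checks enough power to fail loudly if a rule is
broken.

## Coordinates and outputs

Internally every coordinate is 0-based half-open; BED input and output
follow the BED convention, and human-readable reports print 1-based
inclusive positions. Genome coordinates are metadata supplied by the user
(BED6 or a 4-column `name chrom start strand` file; assemblies hg38, hg19,
hg18) — they gate only the UCSC track output, never the analysis. The track
encodes each significant pattern as a BED12 line whose 2 bp blocks mark the
methylated CpGs (with 1 bp anchor blocks added at the window boundaries
where BED12 requires them), score = fraction × 1000, plus one BED6 summary
line per CpG carrying its overall methylation level; this block encoding is
this package's own design, chosen so methylated sites render as filled
boxes in the browser. The figure (`autoplot()`) draws filled/open circles
per pattern row, a green-to-red summary row of per-site levels, blue bars at
variant positions, and per-row support percentages, which need not sum to
100%.

## Known limitations

* No paired-end support; amplicon reads are treated as single-end.
* No differential analysis between samples; comparisons across cell lines
  or conditions are left to the user on the exported tables.
* The identity denominator and the seed length are conventions, not
  derivable from the method's definition; both are exposed as parameters.
* The χ² screen over all site pairs is exploratory and uncorrected by
  design; its p-values should not be reported as confirmatory.
* dbSNP annotation is a positional lookup in a user-supplied local VCF; no
  allele-frequency or strand reconciliation beyond position matching is
  attempted.
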