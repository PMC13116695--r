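---
title: "Methods: diagnostic SNP panels from pooled sequencing"
author: "diagSNP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic SNP panels from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagSNP)
```

## The model

Each species is sequenced as one pooled library of many individuals, so
a sample's data at a called site are read counts, not a diploid
genotype. The quantity the whole package operates on is the pooled
alternate-allele proportion (the "dosage")

$$f_{vs} = \frac{AD^{alt}_{vs}}{AD^{ref}_{vs} + AD^{alt}_{vs}} \in [0,1],$$

treated as an estimate of the population allele frequency of species
$s$ at variant $v$. A marker is useful exactly when these frequencies
are near-fixed in opposite directions across species. Two rules
formalize this:

* **species-specific**: label each species LOW if every replicate pool
  satisfies $f \le t_{low}$, HIGH if every replicate satisfies
  $f \ge t_{high}$, otherwise AMBIGUOUS. A call is made when no species
  is ambiguous and exactly one species sits alone on its side.
* **pairwise**: same labeling, call made when exactly two species sit
  on each side.

The two call sets are structurally disjoint (1-vs-rest versus 2-vs-2
splits). Both rules are invariant under the complement $f \mapsto 1-f$
up to relabeling (targets are preserved; low and high pairs swap), so
whether a published table reports alternate- or reference-allele
frequency does not affect the panel; the package stores alternate-allele
dosage and records that convention in the class documentation.

### Thresholds

$t_{low} = 0.1$ and $t_{high} = 0.9$ are the defaults everywhere
(diagnostic rules and the fixed-site filter share one threshold
vocabulary). They are the loosest round thresholds consistent with the
published panel the package ships as a fixture, where "rare"
frequencies reach 0.05 and "high" ones drop to 0.914. Both are
arguments on every rule-level function.

## The retention cascade

`runCascade()` applies five stages in a fixed order, each a pure
row predicate, with per-stage accounting:

1. **site class** — biallelic SNVs only (exactly one alternate allele,
   both alleles single bases);
2. **depth** — DP strictly greater than 10 in every sample with a
   non-missing genotype (a missing DP in a called sample fails);
3. **fixed sites** — remove variants whose non-missing frequencies are
   all $\ge t_{high}$ or all $\le t_{low}$; sites with no informative
   reads anywhere are removed with them;
4. **flanks** — the closed $\pm 20$ bp window must sit inside one
   covered interval in every sample, contain no other variant site of
   the input table, and contain no N in the reference. "High-quality
   flanking sequence" has no standard operational definition; covered +
   variant-free + N-free is the definition this package commits to;
5. **call rate** — fraction of non-missing genotypes $\ge 0.5$,
   *inclusive*, so that with four samples a variant genotyped in two of
   them survives. (With a strict reading of "greater than 0.5" a
   two-of-four variant would be dropped, contradicting the design goal
   of keeping variants genotyped in at least two samples; the inclusive
   comparison is the deliberate choice.)

Coordinates follow the two file conventions involved: VCF positions are
1-based, BED intervals 0-based half-open, converted in one utility and
nowhere else.

The depth threshold is strict (DP > 10, i.e. at least 11 reads),
following the stated rule rather than the complementary "DP < 10"
shorthand sometimes used in summary tables.

## PCA, distances and ranking

The dosage matrix is transposed to samples × variants, each variant
column centered and scaled to unit sample standard deviation,
zero-variance columns dropped (and reported), and missing values
excluded from the moments then imputed to the column mean — 0 after
centering, the least-informative choice. PCA is singular value
decomposition of that matrix (via `prcomp` on the pre-scaled input);
variance shares are $\sigma_k^2 / \sum \sigma^2$. Component signs are
made deterministic by forcing each loading vector's largest-magnitude
entry positive. Replicate pools of one species are averaged *before*
scaling when a species-level view is wanted (`collapseReplicates =
TRUE`); with four species this leaves at most three non-null
components, which then carry 100% of the variance among themselves.

Marker informativeness is ranked by absolute loading per component,
ties broken by variant id so the ranking is total and reproducible.
Euclidean distances and complete-linkage clustering come from the same
scaled matrix via `dist()`/`hclust()`.

A caution the acceptance checks make explicit: the published
per-component variance shares for this panel (51.12 / 33.81 / 15.07%)
are *not* reproduced by the 27 printed panel variants — the
27-variant × 4-species matrix yields 37.66 / 34.41 / 27.93%, and no
orientation, centering-only, replicate-retaining or complemented
variant of the computation comes close. The published figure was
evidently computed from a larger "most informative" variant set that
was not printed. The package asserts the structural facts it can verify
(three components, shares summing to 100%, TD01–TH04 the closest pair)
and reports the honestly recomputed shares.

## The synthetic-scenario generator

`simulateScenario()` is the package's test bed: it emulates the study
conditions so that every downstream stage has a knowable right answer.

* **Design constants**: four species pools (one replicate each by
  default; a duplicated pool is supported), mean depth 30×, read length
  150 bp — the stated sequencing design.
* **Frequency model**: planted LOW/HIGH frequencies are exactly 0 or 1
  with probability 0.8, otherwise offset from the boundary by
  $0.1 \cdot \mathrm{Beta}(1,3)$ (mean offset 0.025, maximum 0.1).
  This mirrors the published panel, where roughly one entry in five is
  near-fixed rather than fixed, lows reach 0.05 and highs 0.914.
* **Noise modes**: `noiseless` sets alternate reads to the rounded
  expectation $\mathrm{round}(f \cdot DP)$ — appropriate because the
  study's own simulated samples are replications of the observed
  profiles; `binomial` draws $\mathrm{Binomial}(DP, f)$ for robustness
  experiments.
* **Nuisance categories**, each built to be removed by exactly one
  stage: indels and multiallelic sites (site class), DP ≤ 10 in one
  designated sample (depth), all-high frequencies (fixed), positions
  6–15 bp from a coverage-gap boundary (flank), and missing genotypes
  (call rate). Missing-call variants carry *intermediate* frequencies
  (uniform on [0.3, 0.7]) and are missing in a majority of samples:
  with a minority missing they would survive the call-rate stage, and
  with one-sided visible frequencies the fixed-site stage would claim
  them first — either way the category would not isolate the stage it
  exists to test.
* **Coverage model**: every sample covers the genome minus a few
  60 bp gaps whose boundaries jitter ±5 bp per sample, keeping ≥ 95%
  of the genome covered while creating the edge-proximal geometry the
  flank filter must detect.
* **GQ synthesis**: Phred-scaled posterior error of the best of three
  genotype classes under a binomial read model, rounded and capped at
  127, the cap observed in caller output.
* **Determinism**: every stochastic step derives its stream from the
  scenario seed through a fixed offset scheme; the caller's RNG state
  is saved and restored. Identical configurations produce byte-identical
  FASTA/VCF/BED/TSV output.

What the generator does *not* emulate: alignment artifacts, mapping
bias against a diverged reference, per-cycle sequencing error,
paired-end structure, or within-species population structure. Passing
tests on synthetic scenarios therefore demonstrate the correctness of
the *rules*, not the field behavior of the panel on new specimens.

## Simulation-based validation

Pure samples replicate each species' profile (15 per species by
default, 60 in total for four species); mixtures are convex
combinations $p \cdot A + (1-p) \cdot B$ over all unordered pairs at
$p \in \{0.25, 0.5, 0.75\}$ — 18 mixed samples. Equal allocation of the
60 pure samples across species is an assumption (only the total is
fixed by the design) and is configurable. Because projection into PCA
space is affine, a noiseless 50–50 mixture lands exactly at the midpoint
of its parents' scores; the tests assert this to $10^{-8}$.

The classifier is a linear-kernel SVM with unit cost (the reference
implementation in e1071), features unscaled since dosages already live
in $[0,1]$. Mixture predictions are scored against the majority parent,
with either parent accepted at 50–50; no probability calibration is
attempted. On noiseless data the classes are point masses, so perfect
accuracy is the expected outcome and is asserted, not celebrated; the
informative check is ≥ 0.95 accuracy on 200 binomially resampled pure
samples at depth 30.

## Probe extraction

For each diagnostic call, 50 bp of reference sequence is taken on each
side (truncated with a flag at contig ends). A candidate is *clean*
when neither flank contains another variant site or an N; the
per-side *clear run* (distance to the nearest other variant, minus
one) is reported against a default minimum of 25 bp, the conservative
end of the usual 18–25 bp primer-binding requirement. Variants that
survived the 20 bp flank filter necessarily have clear runs of at
least 20 bp; the reconstruction identity
`left + ref + right = reference substring` is asserted for every
candidate.

## Problem sizes and runtime choices

The test suite runs its property checks on deliberately small
instances: 12–20 kb genomes with 15–30 planted variants for the
100-scenario cascade properties, ≤ 10 kb genomes for the brute-force
flank and intersection oracles, 20 scenarios for the binomial-noise
recall bound (call-level recall ≥ 0.9), and 200 noisy samples for the
classification bound. These sizes keep the whole suite within a few
minutes while leaving each property statistically meaningful; all of
them scale linearly if larger instances are wanted.

## Interfaces

The package surface is functions over S4 containers
(`PooledVariants`, `DosageMatrix`, `PCAResult`), with
`runPipeline()`/`pipelineConfig()` as the single-call orchestration and
`scripts/acceptance.R` as the reproduction entry point. File formats go
through the standard Bioconductor parsers (VariantAnnotation for VCF,
Biostrings for FASTA/FASTQ, GenomicRanges for intervals); the VCF/BED
*writers* in the generator emit the minimal standard-conforming subset
those parsers read back verbatim, which the round-trip tests verify.

## Known limitations

* The fixed-site and diagnostic thresholds are shared; a user wanting
  a stricter diagnostic rule than retention rule must run the rules
  separately rather than through `runCascade()` defaults.
* The flank filter's neighbor clause is evaluated against the variant
  table it is given, not against an external exhaustive site list; an
  unascertained variant in real data can therefore hide inside a
  "clean" flank.
* `evaluateReference()` reports each category against the full variant
  set independently; published summary tables of this kind sometimes
  mix sequential and marginal counts, so only the definitions stated in
  its documentation should be compared.
* Site quality ("QUAL < 20") is an exposed, configurable predicate with
  no claim to reproduce any specific caller's quality annotation.
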