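---
title: "Mapping mean- and variance-controlling expression loci in segregant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mean- and variance-controlling expression loci in segregant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlscan)
options(vqtlscan.verbose = FALSE)
```

## The problem and the model

In a two-parent cross of haploid yeast, every segregant carries one of
the two parental alleles (here labelled BY = 0 and RM = 1) at each
marker.  Classical expression-QTL mapping asks, marker by marker,
whether the *mean* log2 expression of a gene differs between the two
genotype classes.  `vqtlscan` additionally asks whether the *variance*
differs — a variance-heterogeneity QTL (vQTL).  Variance heterogeneity
at a locus is interesting because it is a fingerprint of hidden
structure in the genotype class: if locus A only has an effect when
locus B carries a particular allele (epistasis), then a one-dimensional
scan at A sees a mixture distribution in one class and a homogeneous
one in the other, i.e. a variance difference, even when the means barely
move.  vQTL are therefore cheap, one-dimensional pointers to candidate
interacting loci, avoiding the multiple-testing cost of an exhaustive
two-dimensional scan.

Two tests drive the scans:

* **Wilcoxon rank-sum** (mean effects).  Non-parametric, two-sided, with
  the tie-corrected normal approximation and a 0.5 continuity
  correction.  At the panel sizes this package targets (about 55 per
  class) the approximation is excellent; an exact-enumeration mode
  exists for small classes and serves as the test oracle.  Complete
  ties return p = 1: an uninformative marker, not an invalid one.
* **Brown–Forsythe** (variance effects).  A Levene-type test on
  absolute deviations from the class *median*,
  \[
  F = \frac{(N-2)\,\sum_j n_j(\bar z_j - \bar z)^2}
           {\sum_{ij} (z_{ij} - \bar z_j)^2},
  \qquad z_{ij} = |y_{ij} - \mathrm{med}_j|,
  \]
  referred to F(1, N − 2).  The median centring makes the test robust
  to the non-normal, possibly bimodal class distributions that
  epistasis itself produces.

For the AND-type interaction $y = e\,[A{=}1][B{=}1] + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$ with independent, balanced loci, the
marginal class variances at A are $\sigma^2$ and $\sigma^2 + e^2/4$, so
the variance ratio is $1 + e^2/(4\sigma^2)$ — the quantitative link
between epistasis and vQTL that both the simulator and the test suite
exercise.

## Significance by permutation

Genome scans of thousands of phenotypes against thousands of markers
need an empirical null.  The package follows the random-phenotype
permutation design: sample `P_s` phenotypes without replacement,
permute each one's values across segregants `R` times (the study design
uses 200 × 100 = 20,000 permuted scans per test × treatment set), and
re-scan each permuted copy against all markers.  At a threshold $t$,

$$E(t) = \frac{P_{\mathrm{total}}}{P_s}\cdot\frac{1}{R}\sum \#\{p_{\mathrm{null}} \le t\},
\qquad \mathrm{FDR}(t) = E(t) / \#\{p_{\mathrm{obs}} \le t\}.$$

`threshold_for_fdr()` inverts this on the grid of observed p-values.
Two choices deserve mention, both configurable:

* **Counting unit.**  Both numerator and denominator count significant
  *SNP tests*, not merged peaks; peak calling cannot be re-run inside
  20,000 permuted scans at acceptable cost, and the ratio is the same
  under the null to first order.
* **Scaling.**  The `P_total / P_s` factor extrapolates the sampled
  null to the full study; `scale_to_study = FALSE` restricts the
  estimate to the sampled phenotypes.

A Benjamini–Hochberg utility (`bh_threshold()`) is included only as a
cross-check; the permutation route is the package's procedure.

## Peaks, cis/trans, hotspots

Significant SNPs are collapsed greedily: take the unassigned
significant SNP with the smallest p-value (ties broken leftmost by
chromosome order, then position), absorb every unassigned significant
SNP on the same chromosome within ±25 kb, repeat.  This makes the
"peaks 50 kb apart are two peaks" convention automatic: two centers
can only survive if they are more than 25 kb apart each way.  Peaks
never span chromosomes.  A peak is *cis* when its center lies within
150 kb of the affected gene on the same chromosome (inclusive at
exactly 150,000 bp — boundary inclusivity is a deliberate, documented
choice), *trans* otherwise, *unknown* when the gene has no annotated
position; unknowns count in totals but not in cis/trans proportions.
The gene position used is the annotated start.

Hotspot intervals are an *input* (BED): in the study this package
models they were delineated visually, so inferring them would invent
data.  Enrichment uses two 1-df Pearson chi-squares (no Yates
correction by default, given the large counts): observed in/out versus
the hotspot-covered genome fraction, and QTL-versus-vQTL occupancy on
the 2 × 2 table.  Interval membership is 1-based inclusive; a peak
exactly on a boundary is inside.

## The epistasis screen

For each phenotype with a vQTL, two-locus genotype–phenotype (GP) maps
are built for every (vQTL × other peak) pair, and the interaction
contrast
$\Delta = (m_{11} - m_{10}) - (m_{01} - m_{00})$
(three-way alternating sum for three loci) replaces visual map
inspection, flagged at $|\Delta| > 2\,\mathrm{SE}(\Delta)$.  $\Delta$
is invariant to phenotype shifts and to flipping both locus codings,
and changes sign when exactly one coding flips.  Within-class
bimodality is reported only through class SDs and histograms — the
package deliberately ships no formal bimodality test, mirroring the
visual assessment it models.

`conditional_scan()` implements the follow-up used for anchored
epistasis: keep only segregants with a chosen genotype at the anchor
(vQTL) locus, scan the phenotype for mean effects within the subset,
and derive a subset-specific 5% FDR threshold from value permutations
(500 by default, matching the modelled analysis).  Candidate genes for
a peak are all annotated genes whose span *intersects* the ±10 kb
window around the peak center (center, not edges — a documented
choice where the source procedure is ambiguous).

## The synthetic-data generator

Real genotype and expression data for this design are external
downloads, so every stage is exercised against a generator that mimics
the study's statistical structure:

* **Genotypes.**  109 segregants by default; 2956 markers allocated to
  the 16 yeast chromosomes proportionally to their sacCer3 lengths
  (about one marker per 4.1 kb) and spaced evenly.  Each chromosome is
  a two-state Markov chain: first marker Bernoulli(0.5), recombination
  between adjacent markers by the Haldane map function
  $r = \tfrac12(1 - e^{-2d/100})$ at 0.35 cM/kb.  Haldane (no
  interference) is chosen for its closed-form checks; the density is a
  yeast-like order of magnitude and configurable.
* **Expression.**  Gaussian noise on the log2 scale (default SD 0.25,
  a typical residual spread for normalized segregant expression data),
  plus planted architectures: additive cis and trans effects, a shared
  hotspot regulator, AND-type two-locus epistasis, three-locus
  duplicate-factor epistasis (a shift only in the all-BY class), and a
  *direct* variance effect (class-dependent noise SD).  The direct
  vQTL is included even though the modelled analysis attributes vQTL
  to epistasis: the variance scan must detect variance effects
  regardless of mechanism, and the fixture separates the two tests
  (variance signal without mean signal).

What the generator does *not* emulate: array normalization artifacts,
correlated residuals across phenotypes (co-expression), segregation
distortion, and missing genotypes beyond what the caller injects.
Passing tests therefore demonstrate the statistical machinery under
idealized conditions, not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Degenerate cells (a genotype class below `min_class`, default 2)
  yield `NA`, never 0 or 1 — balanced class frequencies hold in a real
  backcross-style panel but not in arbitrary input.  For variance
  tests a floor of 8 per class is a sensible, stricter setting.
* An infinite Brown–Forsythe F (within-class deviations all zero,
  between-class term positive) reports the smallest representable
  positive double, flagged, rather than 0.
* Peak-call tie-breaks are deterministic (leftmost), making runs
  reproducible bit-for-bit given the seed; all randomized stages
  restore the caller's RNG state.
* Coordinates are 1-based inclusive throughout (SGD convention); BED
  is converted on import/export (start = pos − 1).  Missing codes
  accepted on input: `NA`, empty, `-`.

## Problem sizes in the shipped checks

The test-suite and `scripts/acceptance.R` run on reduced but
structurally faithful studies chosen as the package's own validation
sizes: null calibration on 210 phenotypes × 96 widely spaced markers at
n = 109 (≥ 20,000 near-independent test cells — wide spacing across 16
chromosomes keeps the Monte-Carlo check calibrated); a default
synthetic study of 109 × 500 markers with the full architecture set
through the whole pipeline (permutation null 20 × 25 per set); the
AND-model variance-ratio check at n = 2000; and 50–100 replicates of
the conditional-scan recovery design at e/σ = 2.  The full-scale
design (4482 phenotypes × 2956 markers × 2 treatments × 2 tests, with
200 × 100 permutations per set) runs with the same code paths and is
estimated at one to two hours on a single CPU.

## Known limitations

* The Wilcoxon normal approximation degrades below five observations
  per class (absolute p-error up to ≈ 0.04 at 3 + 3); use the exact
  mode there.
* Brown–Forsythe power at n = 109 is modest: a class-SD ratio of 2
  reaches p ≤ 10⁻⁵ in slightly under half of replicates, so a
  genome-wide-significant vQTL at this sample size corresponds to a
  strong variance effect.  Power claims should be read against this.
* The FDR inversion returns the largest observed p-value meeting the
  target; since the empirical FDR curve need not be monotone, sparse
  nulls can admit large-p solutions — inspect `estimate_fdr()` across
  the grid when in doubt.
* The epistasis screen evaluates peaks' center markers only, and GP
  maps use complete cases across the chosen loci.
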