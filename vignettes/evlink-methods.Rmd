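---
title: "Methods: single-EV surface proteomics, denoising, association and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-EV surface proteomics, denoising, association and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlink)
```

This vignette is the package's own account of the statistical methods it
implements: the models, their assumptions, the tunable parameters, the
numerical choices made where the design was genuinely open, and what the
simulation-based tests do and do not establish about real data.

## The measurement model

A proximity barcoding assay labels each extracellular vesicle (EV) with a
unique DNA barcode (the *EV tag*) and each antibody probe with a *protein
tag*; a sequencing read pairs the two. Aggregating read counts over
(EV tag, protein tag) pairs within a sample yields the EV matrix `D`
(m vesicles x n panel proteins, n = 113 by default). Because library depth
varies between samples, counts are normalized by the sample's total reads,
making readouts comparable across samples as proportions. An EV *carries* a
protein when its post-QC count is nonzero; no additional minimum-read rule
is applied, because the chi filter below is the package's single noise
control.

Two conventions matter downstream:

* **EV tags are sample-scoped.** Tags are generated per library, so
  identical tag strings in different samples are different vesicles; no
  cross-sample collision handling is attempted.
* **"Carrying a combination" uses superset matching.** The fraction of EVs
  carrying proteins {A, B} counts every vesicle whose support includes both,
  regardless of other proteins ("at least" semantics). Exact-support
  matching is available (`match_mode = "exact"`) but is not the default,
  since a pair-defined EV population is naturally a sub-population of each
  single-marker population (`quantify_ev_type()` preserves that
  anti-monotonicity, which the test suite checks on simulated matrices).

## Background denoising

Random tag collisions and ambient probes produce spurious EV-protein
incidences. The quality control runs in a fixed order: first EVs with more
than `max_proteins_per_ev` distinct proteins (default 5; boundary strict,
an EV with exactly 5 is kept) are removed as likely aggregates or droplet
artifacts; then the remaining matrix is tested cell-wise against the
independence expectation

\[ E_{ij} = \frac{r_i\,c_j}{N}, \qquad \chi_{ij} = \frac{D_{ij}-E_{ij}}{\sqrt{E_{ij}}}, \]

with \(r_i\), \(c_j\) the row and column sums and \(N\) the grand total.
This is the classical Pearson-residual construction: under independence of
vesicle identity and protein identity (i.e. pure background), the
\(\chi_{ij}\) are approximately standard normal, so genuine biological
co-occurrence shows up as a heavy right tail. Cells with \(\chi\) at or
above the `quantile` level (default 0.95) of the nonzero-cell \(\chi\)
distribution keep their counts; everything else is reset to zero, and
emptied rows are dropped.

Three open choices were settled as follows:

* **Direction of the threshold.** "Keep the top tail" (retain cells at or
  above the 95th percentile, i.e. the top 5%) rather than "keep 95%". Only
  the former produces the order-of-magnitude reduction from raw detected
  EVs to a high-quality subset that motivates the filter in deep-sequenced
  data; both the level and, effectively, the direction are configurable
  through `quantile`.
* **Quantile population.** The percentile is computed over nonzero cells of
  `D` only (`quantile_population = "nonzero_cells"`). In a sparse matrix
  the all-cells quantile is dominated by structural zeros and degenerates
  to 0; the all-cells option exists for dense matrices.
* **Per-sample thresholds.** Each sample's matrix realizes its own cutoff;
  thresholds are not pooled across samples.

Degenerate inputs are defined rather than left to chance: cells with
\(E = 0\) (possible only in an all-zero row or column) have \(\chi = 0\);
an all-equal \(\chi\) distribution retains every cell with a warning; an
explicit `cutoff` argument allows re-applying a previously realized
threshold, which makes the operation idempotent and testable as such.
Conservation \( \sum E = \sum D \) holds to 1e-9 relative tolerance, and on
matrices simulated under row-column independence the surviving-cell
fraction approaches \(1 - q\) (checked at m = 500, n = 50 within 0.05).

## EV phenotypes and their combinatorics

EV types are defined by marker sets of size 1 or 2 (types of cardinality 3
and above are out of scope: vesicles carrying many overlapping proteins
cannot be quantified reliably at routine depth). For a prioritized marker
set M inside a panel of n proteins:

* `marker_pairs_only`: \(|M| + \binom{|M|}{2}\) definitions — 78 for
  12 markers (12 singles + 66 pairs). This is the family used for trait
  association.
* `marker_vs_panel`: all unordered pairs touching M,
  \(|M|(n-|M|) + \binom{|M|}{2}\) — 1278 for 12 markers in a 113-protein
  panel. This is the family scanned in EV genome-wide association work;
  the Bonferroni threshold over it, \(5\times10^{-8}/1278\), rounds to
  \(3.9\times10^{-11}\). (Published accounts of this design sometimes print
  the family size as 1276 after excluding a small number of assay-control
  pairings; the enumeration here returns the literal combinatorial count
  and notes the figure via a message.)

Abundance of a type is the fraction of QC-passed vesicles qualifying —
a proportion of EV *counts*, not of reads, since the phenotype of interest
is "how many vesicles of this kind circulate"; read-weighted levels are
available separately as `total_protein_level()`. Pair labels are
alphabetical, joined by `" & "`, so column names are stable across runs.

## Association model

For each trait Y and exposure X (an EV-type abundance or total protein
level) the package fits, by ordinary least squares,

\[ Y^{*} = \mu + X^{*}\beta_{EV} + \mathrm{Sex}\,\beta_{Sex}
   + \mathrm{Age}\,\beta_{Age} + X^{*}\mathrm{Sex}\,\beta_{EV\times Sex}
   + \varepsilon . \]

* \(Y^{*}\) is the standardized trait. Standardization uses the sample
  (n-1) standard deviation — the default of standard statistical
  environments — and the convention is recorded in the output's attributes.
* \(X^{*}\) is the rank-based inverse normal transform
  \(\Phi^{-1}\!\big((r - 0.5)/n\big)\) with average ranks for ties. The
  offset 0.5 is the common default; any monotone transform of the raw
  abundances yields identical results, which is the point: EV abundances
  are heavily skewed proportions, and only their ordering is trusted.
* Sex is coded male = 1, female = 0, so a positive interaction coefficient
  means the exposure's effect is weaker in men than in women.
* Missing data are handled by listwise deletion per trait-exposure pair,
  and the n actually used is reported; fits require n > 5 (five
  coefficients) and fail loudly on singular designs, naming the collinear
  column.

The per-association effect size reported as "R²" is the **squared
semi-partial correlation of the EV main-effect term**: the drop in residual
sum of squares when \(X^{*}\) enters last, divided by the total sum of
squares. With the interaction term in the model, \(X^{*}\) and
\(X^{*}\mathrm{Sex}\) are strongly collinear (r ≈ 0.7 with balanced sexes),
so a large \(\beta_{EV}\) can coexist with a modest unique-variance share —
e.g. a true \(\beta_{EV} = -1.62\) with residual sd 2.26 gives a partial R²
near 0.17. The full-model R² is also emitted. Multiplicity is controlled by
Benjamini-Hochberg step-up q-values, by default pooled across the entire
family of total-protein and EV-specific tests (`family = "pooled"`); a
per-trait family is available.

## Genetics

EV phenotypes enter genome scans as Z-scores: OLS residuals on sex, age and
any experimental factors, inverse-normal transformed. This residual hook is
also where externally pre-adjusted phenotypes (e.g. mixed-model
kinship-corrected residuals from a family-structured cohort) plug in; the
package itself does not model relatedness, because its simulated cohorts
are unrelated by construction and the scan's calibration
(genomic-control \(\lambda \approx 1\)) then holds without correction.

The scan is per-SNP simple linear regression in closed form (slope,
standard error, two-sided t-test), vectorized over SNPs; the test suite
verifies agreement with `lm()` and with \((X'X)^{-1}X'y\) to 1e-10
relative. MAF filtering is strict (`maf > threshold`), with both
conventional defaults exposed: 0.05 for general QC and 0.2 for small-sample
EV scans, where rare variants inflate false positives.

SNP sets are built per marker: the union, over all pair phenotypes
containing the marker, of SNPs with \(P\) below `p_threshold` (default
1e-6), deduplicated within the set; a thirteenth set pools the
marker-marker pair phenotypes. Whether deduplication should happen before
or after any clumping is an open question in the published design;
union-with-dedup is implemented. Sets are annotated with ±1 kb flanks
(intervals 0-based half-open, clipped at zero, merged per chromosome via
`IRanges::reduce`), and every panel SNP inside a merged interval becomes
annotation-positive.

Heritability enrichment is the share of trait heritability carried by
annotation-positive SNPs divided by the share of SNPs annotated, with a
leave-one-block-out jackknife SE over (by default) 200 contiguous SNP
blocks. The package deliberately scores enrichment **directly on simulated
per-SNP heritability truth** rather than re-implementing stratified LD-score
regression: with genotypes simulated as independent Hardy-Weinberg biallelic
SNPs (no LD), the direct estimator is unbiased and exactly checkable
(score 1 for an all-SNP annotation; score 4 when all heritability sits in a
25%-of-SNPs annotation; mean 1 under random annotations), and a planted
architecture with heritability share f in SNP share s recovers f/s — the
package's property-based stand-in for observed 2-4-fold enrichment regimes.

## What the simulator emulates — and what it does not

`simulate_ev_sample()` draws, per EV, a distinct-protein count k from a
configurable distribution, then k panel proteins without replacement
(optionally weighted by a pairwise co-occurrence matrix, each next protein
drawn with weight proportional to the product of its weights with the
already-picked ones), then a read count per true incidence (default
1 + Poisson(2), support ≥ 1 so every true incidence is observed), and
finally adds a `noise_rate` fraction of reads uniformly over (existing EV
tag, random protein) pairs. The default k-distribution is a 62% point mass
on singletons plus a negative-binomial-shaped remainder over 2..20 with
mode near 5 — matching the qualitative shape of deep-sequenced plasma EV
populations: a singleton majority, ~96% of vesicles carrying 1-10 proteins,
multi-protein mode at 5-6. (A single zero-truncated negative binomial
cannot satisfy both the 62% singleton mass and a non-singleton mode at 5-6,
hence the explicit mixture. Published summaries of such data also contain a
second, hard-to-reconcile singleton figure of ~50%; the generator targets
62% and exposes the mass as a parameter.) The ground truth (EV → protein
multiset) is retained for every sample, and the empirical k-distribution
passes a chi-square goodness-of-fit test at n = 1e5 EVs with zero noise.

Note that background noise *lowers* the observed singleton fraction (noise
reads add spurious proteins to existing vesicles), so distribution-level
checks condition on `noise_rate = 0`.

`simulate_cohort()` generates unrelated individuals (sex Bernoulli, age
uniform over 16-100 years, matching a general adult cohort), EV abundances
as a genetic value plus unit-variance latent noise mapped monotonically to
a proportion scale (rank-preserving, so inverse-normal-based analyses are
unaffected by the mapping), traits from declared \(\beta_{EV}\),
\(\beta_{EV\times Sex}\), sex and age effects plus Gaussian noise, and a
scalar complex trait \(Gb + e\) whose residual variance is set so the
realized genetic-variance share equals the requested h²; per-SNP
heritability contributions are recorded as enrichment truth.

What the simulations do **not** emulate — and therefore what passing tests
do not establish about real data: linkage disequilibrium (the enrichment
estimator's unbiasedness leans on its absence), relatedness and population
structure, sequencing error in tag sequences, depth-dependent dropout of
high-multiplicity vesicles, batch effects between replicates, and any
specific biology of the marker panel. Results on real cohorts additionally
depend on the kinship correction applied upstream of the Z-score hook.

## Numerical choices and problem sizes

Fixed conventions, in one place: sample-sd standardization; INT offset
(r-0.5)/n with average-rank ties; strict inequalities at the max-proteins
and MAF boundaries; chi threshold retention is "at or above" the realized
cutoff; quantiles use R's default (type 7) estimator; E-conservation
tolerance 1e-9 relative; positions 0-based half-open internally, converted
at VCF/BED boundaries; canonical orderings everywhere (types sorted by
size then label; EV tags sorted lexically) so reruns are byte-identical
under a fixed seed, with per-stage seeds derived deterministically from the
pipeline's global seed.

The test and acceptance suites run at deliberately desk-scale sizes chosen
to make each statistical property measurable with comfortable Monte-Carlo
margins: 1e5 EVs for distribution summaries, m = 500 x n = 50 for the
chi-filter tail property, n = 96 individuals (the motivating cohort size)
with 1000-2000 replicates for coverage and type-I error, 5000 SNPs for null
scan calibration, and 1000 SNPs with 200 jackknife blocks for enrichment.
The effect magnitudes exercised (\(\beta_{EV} = -1.62\) with partial
R² ≈ 0.17, stronger pair-type effects near -2.31) mirror the regime the
package is designed for.

## Known limitations

* The chi filter assumes background follows row-column independence; true
  structured contamination (e.g. ambient probe families) is not modeled,
  and alternative denoisers (EM mixtures, ambient deconvolution) are out of
  scope.
* Whether per-protein carriage summaries should be computed before or after
  the chi filter is analysis-dependent; both orders are supported, and the
  package does not take a side.
* Enrichment SEs from the block jackknife are approximate when annotations
  are strongly clustered along the (synthetic) genome.
* The conversion between standardized-trait effect sizes and
  "SD-per-SD" restatements sometimes quoted alongside them is not
  derivable from the quantities the package computes, and is deliberately
  not reproduced.
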