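---
title: "Methods: mapping-by-sequencing of pooled F2 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping-by-sequencing of pooled F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsmap)
```

## The experimental design this package analyses

Bulk segregant analysis (also called mapping-by-sequencing, MBS)
localizes the loci behind a quantitative trait without genotyping
individuals. Two homozygous parental lines contrasting for the trait
are crossed; the F2 generation segregates; the phenotypic extremes of
the F2 — the *tails* — are pooled and whole-genome sequenced together
with both parents. At a marker linked to a trait locus, the selected
pools inherit the two parental alleles at skewed frequencies, and the
skew decays with recombination distance. The analysis therefore
reduces to estimating, for every parent-contrasting SNV, the
alternate-allele read frequency in each pool and asking where along
the genome the two pools disagree more than sampling noise allows.

`mbsmap` implements that analysis as a chain of small, testable
stages, each exposed as plain functions over data frames.

## Gold standard: which SNVs are worth scoring

Raw pool variant calls are dominated by sites that cannot carry
mapping signal: sites not actually contrasting between the parents,
paralogous pile-ups, and miscalled repeats. The whitelist ("gold
standard") keeps a site when:

1. exactly one parent is homozygous for an alternate allele
   (`filter_parental_variants()` + `combine_parental_sets()`).
   Sites homozygous-alternate in *both* parents are excluded — with
   the same allele they do not contrast, with different alleles the
   site is triallelic and its frequency estimates are unreliable;
2. the parent's read depth lies in **[10, 60]** — the lower bound
   guards genotype quality, the upper bound (about twice the modal
   depth of a typical parental run) removes copy-number-inflated
   sites;
3. the *reconstituted F1* — obtained by summing both parents' ref and
   alt read counts per site (`reconstitute_f1()`) — looks
   heterozygous there, with an alternate-allele frequency in
   **[0.2, 0.8]**. A truly contrasting site must be heterozygous in
   the F1; a skewed F1 frequency betrays mapping bias.

Three choices here were genuinely open and are worth recording:

* **Band inclusivity.** Both the depth band and the F1 frequency band
  are closed intervals. The permissive reading costs nothing at the
  boundaries and keeps the bands single-knob configurable.
* **Homozygosity source.** The caller's `GT` field decides; when it
  is missing, an alternate-read fraction ≥ 0.9 is accepted as
  homozygous. Callers occasionally emit `./.` at well-covered sites
  and discarding those wholesale would bias the whitelist.
* **F1 composition.** The reconstituted F1 sums the *parental* reads
  by default; pool reads can be added through `extra_counts`. A
  parents-only F1 keeps the unit self-contained and makes the
  whitelist independent of the pools it later filters.

## Pool statistics and the delta allele frequency

Each pool is restricted to whitelist SNVs and to a depth band of
**0.75×–1.5× the pool's own median depth** over whitelist sites
(`filter_pool_variants()`; bounds inclusive). The median is computed
per pool rather than pooled across both, so a pool sequenced deeper
is not trimmed against the other's depth; a shared mean-of-medians is
a one-line change if desired.

The two pools are inner-joined on position, requiring an identical
single alternate allele on both sides (`join_pools()`). For each
joined site the allele frequency is the alternate read fraction and
the **delta allele frequency** is

dAF = |AF_high − AF_low|.

The absolute value makes the statistic orientation-free: no
parent-of-origin polarization is needed, and a locus where the
*low* pool carries the alternate allele scores identically.

## dARC calling

A dAF alone does not separate signal from binomial noise at finite
depth. Each site's 2×2 table of (ref, alt) read counts in the two
pools is tested with a **two-sided Fisher's exact test**
(`fisher_exact_2x2()`, backed by `stats::fisher.test`), corrected for
multiple testing, and flagged significant below **α = 0.05**
(`call_darcs()`). Passing sites are *dARCs* — differential
allele-specific read counts.

The correction method is **Benjamini–Hochberg by default** with
Bonferroni as an option. With ~10^5–10^6 tests genome-wide and many
truly linked sites, FDR control is the field's standard compromise;
Bonferroni is provided for users who want family-wise control at the
cost of sensitivity near interval edges. The test is two-sided
because direction is recovered later from the frequencies themselves.
All-zero tables are undefined and are dropped with a message rather
than silently scored.

## Interval detection

dARC positions are clustered per chromosome with three rules
(`cluster_darcs()`, `validate_cluster()`):

* **gap rule** — adjacent dARCs within a cluster must be strictly
  less than **50 kbp** apart; a gap of exactly 50 kbp splits. This
  stops sparse dARC runs from bridging unrelated dense regions.
* **count rule** — a cluster needs at least **4** dARCs.
* **spread rule** — at least **3** member dARCs must be pairwise more
  than **1 kbp** apart. Several variants called from one sequenced
  fragment can be a single artifact; demanding spread de-duplicates
  them. The decision procedure is the greedy left-to-right scan that
  keeps each dARC more than 1 kbp beyond the last kept one; on a
  line, greedy selection finds the maximum well-spread subset, so
  this is exact, and the test suite checks it against exhaustive
  subset enumeration. An alternative reading of the rule (cluster
  *span* > 1 kbp) is strictly weaker and was rejected because it
  admits two-fragment artifacts.

**Zero-coverage regions** (ZCRs) are scanned beforehand
(`detect_zcrs()`): non-overlapping 200 bp windows, tiled from
position 1, in which *every* base has zero depth in *both* pools
(a trailing partial window is not evaluated). Such regions —
typically deletions shared by both parents — cannot contain variants
and therefore split genuine intervals. Two adjacent clusters are
re-merged when at least **50%** of the gap between them is covered by
ZCRs (`merge_across_zcrs()`, iterated to a fixed point). The merge
fraction is this package's own parameter: the underlying idea (ZCRs
explain interval splits) dictates *that* one merges, not *when*, and
half-covered is the point where the ZCR explanation becomes the
dominant account of the gap. "Extremely low but nonzero" coverage is
deliberately not ZCR material — that evidence belongs to the PAV
caller below.

Surviving clusters become intervals whose boundaries are the first
and last member dARC and whose reported size is `end − start`.
Intervals are thresholded by a minimum dARC count (the reference
analyses used 100 and 65 for their two traits; the package default is
the seeding minimum 4, and the threshold is a plain argument), ranked
by descending dARC count with ties broken by larger size then smaller
start, and labelled `<chromosome>_<trait>_<k>` with `k` numbering
intervals along each chromosome by start position.

## Coverage analysis: presence–absence variations

A gene deleted in one parent shows a read-coverage contrast between
oppositely selected pools. `detect_pavs()` computes each gene's mean
depth per pool, normalizes by the pool's genome-wide mean depth, and
calls a PAV when

* the raw mean depth in at least one pool is below **mincov = 10**
  reads, and
* the normalized depths differ at least **2-fold**.

In an F2, a single-parent deletion under opposite selection is
expected near pool deletion-allele frequencies of roughly 3/4 vs 1/4,
i.e. the depleted pool retains about **1/3** of the other pool's
normalized coverage; the 2-fold floor admits that expectation with
sampling noise while rejecting ordinary depth wobble. Calls are
ranked by descending normalized ratio — the contrast itself is the
natural ranking statistic in the absence of a published one. Genes
with zero coverage in *both* pools (shared deletions) show no
contrast and are not PAVs; they surface as ZCRs instead.

## Reporting tracks

* `smooth_daf()` — the median dAF in sliding windows of **100
  variants** advancing **5 variants** per step (variant-count
  windows, not bp). The median is robust to isolated outliers; a
  chromosome with fewer variants than one window yields an empty
  track with a warning, and a trailing partial window is dropped, so
  the track length is exactly `floor((n − 100)/5) + 1`.
* `darc_density()` — dARCs divided by all SNVs in **100 kbp** windows
  stepping **30 kbp**. Windows without any SNV emit `NA`, not 0:
  variant deserts must stay visually distinct from regions that
  merely lack significant sites.
* `normalized_mean_coverage()` — window mean depth divided by the
  chromosome's maximum window mean, so the best-covered window is
  exactly 1 and an all-zero chromosome stays all-zero without a
  division by zero.
* All bp windows are anchored at position 1 with a fixed step; the
  anchor is a convention, stated here so tracks from different runs
  align.

Candidate genes are collected per interval as every gene whose body
overlaps the interval extended by **±5 kbp** by at least one base
(`extract_candidate_genes()`): overlap semantics, not containment, so
genes spanning a border are kept, and a gene merely touching the
flank boundary is included. High-impact variants are filtered from
SnpEff-style `ANN` annotations to exactly four classes — stop gained,
stop lost, frameshift, splice donor/acceptor — with other
nominally-HIGH classes excluded by default since the supported
class list is deliberately explicit (`filter_high_impact()`).

## The simulator: what it emulates, and what it does not

`simulate_f2()` generates the full experiment from a `sim_config()`:

* SNVs placed uniformly at the configured density; each site's
  alternate allele assigned to a random parent, the other parent
  matching the reference;
* F1 gametes with **Haldane** crossovers (Poisson-many, uniformly
  placed, no interference) at `cm_per_mb` — chosen for closed-form
  checkability: the recombination fraction at distance *d* cM is
  `r = (1 − e^(−2d/100))/2`, which `expected_pool_af()` combines with
  the truncated-selection causal pool frequency
  (`causal_pool_af()`) into an exact expectation for any linked
  marker;
* an additive phenotype (optional pairwise epistasis via the
  `epistasis` term) plus Gaussian noise; pools are the phenotype
  tails;
* read counts per pool site drawn binomially at Poisson depth from
  the pool's true allele frequency, with an optional per-read error
  flip;
* deletions whose carrier haplotypes contribute no reads: shared
  deletions give exactly zero coverage, single-parent deletions scale
  depth by the pool's present-haplotype fraction (evaluated on a
  200 bp grid inside deletion regions — crossovers within a deletion
  are rare enough that this resolution is exact in practice).

Default conditions: one 20 Mbp chromosome, 1 SNV/2 kbp, F2 of 1000,
5% tails, 50× depth, 2 cM/Mbp (a typical *Brassica*-scale
recombination rate), one central causal locus of effect 1 against
residual s.d. 0.5 (heritability 2/3). With a fixed seed the output is
bit-reproducible.

What the simulator does **not** emulate — and hence what passing
tests do not show about real data: allopolyploid homoeologous
mis-mapping (the dominant noise source in a real *Brassica* genome),
reference bias, indel-induced alignment artifacts, library and GC
coverage waves, and polygenic trait architecture beyond a handful of
additive loci. The pipeline's filters exist largely *because* of
those artifacts; the simulation shows the machinery is correct, not
that the filters are sufficient for any particular genome.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (VCF/GFF3
  convention); only BED export converts to 0-based half-open.
* Multiallelic VCF records are rejected, not split, with a count
  reported — consistent with the triallelic exclusion in the gold
  standard.
* Interval tie-breaks (equal dARC count): larger size, then smaller
  start — deterministic output ordering.
* `pool_median_coverage()` uses R's even-length median (mean of the
  central pair); an empty pool is fatal rather than `NA`.
* Fisher p-values on all-zero tables are undefined → record dropped
  with a message; `adjust_pvalues()` refuses p ∉ (0, 1].
* Problem sizes in the test suite are chosen to exercise every rule
  at desk scale: the parameter-recovery study runs 50 seeded
  simulations of the default configuration; structural-variant
  checks use a 2 Mbp chromosome at 30× with an F2 of 2000. The 30×
  depth in the structural fixture is deliberate: with ~3/4 vs ~1/4
  pool frequencies at the deletion, the depleted pool's raw mean
  (~8×) falls below the mincov gate, which at 50× (~13×) it would
  not — the gate is a *raw-depth* criterion, exactly as in gene-mode
  PAV scanning practice.

## Known limitations

* The Fisher test treats reads as independent draws from the pool;
  overdispersion from unequal individual contributions to the pool
  DNA is not modelled, so genome-wide significance on real data is
  anti-conservative to an unknown degree — the interval rules
  (count, spread, gap) are the practical guard.
* ZCR detection is strict-zero; a single stray mismapped read
  suppresses a window. Window size 200 bp is the only lever.
* The PAV ranking statistic (normalized ratio) saturates at `Inf`
  when one pool has zero gene coverage; rank among `Inf` calls then
  falls back to position order.
* Interval IDs renumber per chromosome on every run; they are stable
  only for a fixed input.
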