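# mbsmap

Mapping-by-sequencing (bulk segregant analysis) of pooled F2
populations in R.

## The problem

Breeders and geneticists localize the loci behind a quantitative
trait by crossing two contrasting homozygous parents, phenotyping a
large segregating F2 population, and whole-genome sequencing two DNA
pools drawn from the phenotypic extremes together with both parents.
Near a trait locus, the selected pools inherit the parental alleles
at skewed frequencies; away from it, recombination returns both
pools to 1:1. `mbsmap` turns the variant calls and coverage tracks of
such an experiment into ranked trait-associated genomic intervals,
candidate genes, and structural-variant calls. It is aimed at people
running pool-seq mapping experiments in crops or other crossable
organisms, and at methodologists who want every stage of that
analysis as a small, separately testable function.

## The method

For each biallelic SNV the alternate-allele read frequency is
computed per pool, and the contrast between pools is measured by the
**delta allele frequency**

&nbsp;&nbsp;&nbsp;&nbsp;dAF = |AF_high − AF_low|,&nbsp;&nbsp; AF = alt reads / (ref + alt reads),

restricted to a **gold standard** of SNVs that are homozygous and
contrasting between the parents (depth 10–60) and heterozygous
(AF 0.2–0.8) in the reconstituted F1. Significance is assessed per
site by a two-sided **Fisher's exact test** on the 2×2 table of pool
allele counts with Benjamini–Hochberg correction (α = 0.05); passing
sites are **dARCs** (differential allele-specific read counts).
dARCs are clustered into genomic intervals by three rules — adjacent
dARCs < 50 kbp apart, ≥ 4 dARCs per interval, ≥ 3 of them pairwise
> 1 kbp apart — with clusters re-merged across zero-coverage regions
(200 bp windows with no reads in either pool), then ranked by dARC
count. Coverage tracks additionally yield gene-level
presence–absence variations: genes with raw mean depth < 10 in one
pool and a ≥ 2-fold normalized coverage contrast (an F2 deletion
under opposite selection is expected near 3-fold). A seeded F2
simulator (Haldane recombination, phenotype-tail selection, binomial
read sampling at Poisson depth, engineered deletions) generates
complete experiments with truth tables, so the whole chain is
testable without sequencing data.

See `vignettes/mbsmap-methods.Rmd` for the full methods account.

## Worked example

Simulate a small experiment — one 5 Mbp chromosome, an F2 of 500
with a single major locus at 2.5 Mbp, 5% tails at 50× — and run the
full pipeline:

```r
library(mbsmap)

cfg <- sim_config(chrom_length = 5e6, n_f2 = 500L, seed = 11)
sim <- simulate_f2(cfg, coverage = FALSE)
res <- run_mbs_pipeline_sim(sim, trait_label = "SIM")

res$gold
#> <gold_standard> 2315 contrasting SNVs
#>   n_input_p1: 2500
#>   n_input_p2: 2500
#>   n_pass_p1: 1153
#>   n_pass_p2: 1162
#>   n_contrasting: 2315
#>   n_absent_from_f1: 0
#>   n_af_outside: 0
#>   n_final: 2315

res$intervals
#>   interval_id chrom start     end    size n_darcs rank
#> 1    01_SIM_1 chr01  1153 4999157 4998004    2162    1
```

Reading the numbers: of the 2 × 2500 simulated parental records,
1153 + 1162 pass the per-parent depth/homozygosity filter (each
parent is homozygous-alternate at roughly half the sites and the
Poisson(50) depth tail crosses the 60× ceiling at the rest); 2315
contrasting sites survive the F1 heterozygosity screen and form the
whitelist. After pool filtering and joining, 2162 sites are tested
and all are significant — on a 10 cM chromosome with a major locus
(here dAF = 1.0 at the site nearest the locus), every site is
linked to it — so the top-ranked (and only) interval spans the
chromosome and contains the causal position. On multi-chromosome
input, unlinked chromosomes contribute no dARCs and drop out.

The `analysis/` directory holds the same workflow as numbered
drivers (`01_simulate.R` … `05_structural_variants.R`) that write
their tables under `results/`.

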