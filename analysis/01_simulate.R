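#!/usr/bin/env Rscript

# Step 1: generate the simulated mapping-by-sequencing experiment that
# the rest of the workflow analyses.
#
# One 20 Mbp chromosome, one SNV per 2 kbp segregating between two
# homozygous parents, an F2 of 1000 plants phenotyped on a single
# major additive locus (heritability 2/3), 5% tails pooled on each
# side and sequenced at 50x. Variant tables are written as VCF so the
# downstream steps exercise the same readers a real experiment would.

suppressPackageStartupMessages(library(mbsmap))

cfg <- sim_config(seed = 1L)
sim <- simulate_f2(cfg, coverage = FALSE)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
paths <- write_simulation(sim, "results/sim")

ts <- sim$truth$sites
i <- which.min(abs(ts$pos - cfg$causal_loci$pos))
cat(sprintf("simulated %d SNV sites on %d chromosome(s)\n",
            nrow(ts), cfg$n_chromosomes))
cat(sprintf("pools: %d (high) / %d (low) of %d F2 plants\n",
            length(sim$truth$high_idx), length(sim$truth$low_idx),
            cfg$n_f2))
cat(sprintf("causal locus at %s:%d; nearest site true pool AFs %.2f / %.2f\n",
            cfg$causal_loci$chrom, cfg$causal_loci$pos,
            ts$af_high[i], ts$af_low[i]))
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
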