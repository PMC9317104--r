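#!/usr/bin/env Rscript

# Step 3: filter the pool variants against the gold standard and the
# per-pool coverage band (0.75x-1.5x the median), join the pools,
# compute delta allele frequencies, and call dARCs with Fisher's exact
# test + Benjamini-Hochberg correction at alpha 0.05. Also writes the
# smoothed dAF track (100-variant windows, 5-variant steps) and the
# normalized dARC density (100 kbp windows, 30 kbp steps).

suppressPackageStartupMessages(library(mbsmap))

gold <- utils::read.table("results/gold_standard.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
high <- read_vcf("results/sim/pool_high.vcf", "POOL_HIGH")
low <- read_vcf("results/sim/pool_low.vcf", "POOL_LOW")

fh <- filter_pool_variants(high, gold)
fl <- filter_pool_variants(low, gold)
cat(sprintf("pool filter: high %d -> %d (median depth %.0f), low %d -> %d (median depth %.0f)\n",
            nrow(high), nrow(fh), attr(fh, "median_coverage"),
            nrow(low), nrow(fl), attr(fl, "median_coverage")))

joined <- join_pools(fh, fl)
cat(sprintf("joined biallelic sites: %d; mean dAF %.3f, max dAF %.3f\n",
            nrow(joined), mean(joined$daf), max(joined$daf)))

darcs <- call_darcs(joined, alpha = 0.05)
utils::write.table(darcs, "results/darcs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

smooth <- smooth_daf(joined)
truth <- jsonlite::read_json("results/sim/truth.json",
                             simplifyVector = TRUE)
dens <- darc_density(darcs$pos[darcs$is_darc], joined$pos, "chr01",
                     truth$chrom_lengths$chr01)
utils::write.table(smooth, "results/smoothed_daf.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(dens, "results/darc_density.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("peak smoothed dAF %.3f at %s:%d\n",
            max(smooth$value),
            smooth$chrom[which.max(smooth$value)],
            smooth$window_start[which.max(smooth$value)]))
cat("wrote results/darcs.tsv, results/smoothed_daf.tsv, results/darc_density.tsv\n")
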