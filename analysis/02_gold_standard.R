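#!/usr/bin/env Rscript

# Step 2: build the gold-standard SNV whitelist from the parental
# variant calls: homozygous and contrasting between the parents
# (depth 10-60), heterozygous (allele frequency 0.2-0.8) in the
# reconstituted F1.

suppressPackageStartupMessages(library(mbsmap))

p1 <- read_vcf("results/sim/parent1.vcf", "P1")
p2 <- read_vcf("results/sim/parent2.vcf", "P2")

gold <- build_gold_standard(p1, p2)
cnt <- attr(gold, "counters")

dir.create("results", showWarnings = FALSE)
utils::write.table(as.data.frame(gold), "results/gold_standard.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("gold standard:", nrow(gold), "contrasting SNVs\n")
cat(sprintf("  parent depth filter kept %d / %d (P1) and %d / %d (P2)\n",
            cnt[["n_pass_p1"]], cnt[["n_input_p1"]],
            cnt[["n_pass_p2"]], cnt[["n_input_p2"]]))
cat(sprintf("  %d sites dropped outside the F1 AF band, %d absent from F1\n",
            cnt[["n_af_outside"]], cnt[["n_absent_from_f1"]]))
cat("wrote results/gold_standard.tsv\n")
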