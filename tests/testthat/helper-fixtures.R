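# Shared fixture builders for the test suite. Everything is generated
# in code; no binary files.

# Write a toy single-sample VCF from parallel vectors; fields default
# to a clean biallelic SNV record.
write_toy_vcf <- function(path, chrom, pos, ref, alt, ad, gt,
                          sample = "S1", info = ".") {
  n <- length(pos)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Annotation">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (n == 0L) character() else {
    paste(chrom, pos, ".", ref, alt, ".", "PASS",
          rep_len(info, n), "GT:AD",
          paste0(gt, ":", ad), sep = "\t")
  }
  writeLines(c(header, body), path)
  path
}

# Minimal variant data.frame in the internal layout.
make_variants <- function(chrom = "chr01", pos, ref = "A", alt = "T",
                          ref_count = 10L, alt_count = 10L,
                          genotype = "het", type = "snv",
                          filter_status = "PASS") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             ref = rep_len(ref, length(pos)),
             alt = rep_len(alt, length(pos)),
             ref_count = rep_len(as.integer(ref_count), length(pos)),
             alt_count = rep_len(as.integer(alt_count), length(pos)),
             filter_status = rep_len(filter_status, length(pos)),
             genotype = rep_len(genotype, length(pos)),
             type = rep_len(type, length(pos)),
             stringsAsFactors = FALSE)
}

# Independent two-sided Fisher oracle: exhaustive enumeration of all
# 2x2 tables with the observed margins, summing hypergeometric
# probabilities no larger than the observed table's (with the usual
# relative tolerance against floating-point ties).
fisher_oracle <- function(ref_h, alt_h, ref_l, alt_l) {
  row1 <- ref_h + alt_h
  row2 <- ref_l + alt_l
  col1 <- ref_h + ref_l
  n <- row1 + row2
  k_range <- max(0L, col1 - row2):min(row1, col1)
  probs <- vapply(k_range, function(k) {
    exp(lchoose(row1, k) + lchoose(row2, col1 - k) - lchoose(n, col1))
  }, numeric(1L))
  p_obs <- probs[match(ref_h, k_range)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Fixture configuration for structural-variant tests: a 2 Mbp
# chromosome at 30x with a moderate-effect locus placed at a
# single-parent deletion (expected pool deletion-allele frequencies
# ~0.73/0.27, hence a ~2.7-fold normalized coverage contrast), plus a
# 10 kbp deletion shared by both parents on the 200 bp window grid.
sv_fixture_config <- function(seed = 20260924) {
  sim_config(
    n_chromosomes = 1L, chrom_length = 2e6, snv_density = 1 / 2000,
    n_f2 = 2000L, tail_low = 0.05, tail_high = 0.05,
    causal_loci = data.frame(chrom = "chr01", pos = 850000,
                             effect = 0.5, stringsAsFactors = FALSE),
    residual_sd = 1, mean_depth = 30, cm_per_mb = 2,
    deletions = data.frame(
      chrom = "chr01",
      start = c(200001L, 820001L),
      end = c(210000L, 880000L),
      carrier = c("both", "p1"),
      stringsAsFactors = FALSE
    ),
    seed = seed
  )
}
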