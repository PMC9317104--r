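test_that("dAF smoothing uses variant-count windows with fixed step", {
  rec <- data.frame(chrom = "chr01", pos = seq_len(100) * 10,
                    daf = rep(0.3, 100))
  tr <- smooth_daf(rec)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$value, 0.3)

  rec105 <- data.frame(chrom = "chr01", pos = seq_len(105) * 10,
                       daf = runif(105))
  tr105 <- smooth_daf(rec105)
  expect_equal(nrow(tr105), 2L)  # floor((105 - 100) / 5) + 1
  expect_equal(tr105$window_start, c(10, 60))

  # one outlier among 99 quiet sites does not move the median
  daf <- c(rep(0.1, 50), 1.0, rep(0.1, 49))
  rec_out <- data.frame(chrom = "chr01", pos = seq_len(100), daf = daf)
  expect_equal(smooth_daf(rec_out)$value, 0.1)

  short <- data.frame(chrom = "chr01", pos = 1:10, daf = 0.5)
  expect_warning(tr0 <- smooth_daf(short), "empty track")
  expect_equal(nrow(tr0), 0L)
})

test_that("smoothed window count matches the closed form", {
  set.seed(51)
  for (n in c(100, 137, 250, 999)) {
    rec <- data.frame(chrom = "chr01", pos = seq_len(n), daf = runif(n))
    expect_equal(nrow(smooth_daf(rec)), floor((n - 100) / 5) + 1)
  }
})

test_that("dARC density divides dARCs by SNVs, NA on empty windows", {
  snvs <- c(seq(1, 90000, by = 2000), seq(300001, 360000, by = 1200))
  darcs <- snvs[snvs <= 90000][1:10]
  tr <- darc_density(darcs, snvs, "chr01", 400000)
  w1 <- tr$value[tr$window_start == 1]
  expect_equal(w1, 10 / sum(snvs <= 100000))
  # window 120001-220000 has no SNVs at all -> NA, not 0
  expect_true(is.na(tr$value[tr$window_start == 120001]))
  # dARCs are a subset of SNVs: density never exceeds 1
  expect_true(all(tr$value[!is.na(tr$value)] <= 1))
  full <- darc_density(snvs, snvs, "chr01", 400000)
  expect_true(all(full$value[!is.na(full$value)] == 1))
})

test_that("normalized window coverage peaks at exactly 1", {
  tr <- coverage_track("chr01", rep(20L, 400000), "high")
  nm <- normalized_mean_coverage(tr)
  expect_true(all(nm$value == 1))

  depth <- rep(25L, 400000)
  depth[1:100000] <- 50L
  nm2 <- normalized_mean_coverage(coverage_track("chr01", depth, "h"))
  expect_equal(max(nm2$value), 1)
  expect_equal(nm2$value[nm2$window_start == 1], 1)
  expect_equal(min(nm2$value), 0.5)

  zero <- coverage_track("chr01", integer(200000), "h")
  expect_true(all(normalized_mean_coverage(zero)$value == 0))
})

test_that("candidate gene extraction uses inclusive flank overlap", {
  iv <- data.frame(interval_id = "I1", chrom = "chr01",
                   start = 100000, end = 200000, stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("touch_left", "inside", "too_far", "span_right"),
    chrom = "chr01",
    start = c(90000, 150000, 94000, 204000),
    end = c(95000, 151000, 94999, 210000),
    strand = "+", annotation = "", stringsAsFactors = FALSE
  )
  hits <- extract_candidate_genes(iv, genes, flank = 5000)
  # gene ending exactly at start - 5000 touches the flank -> included
  expect_setequal(hits$gene_id, c("touch_left", "inside", "span_right"))
  # flank 0 result is a subset of the flank-5kb result
  hits0 <- extract_candidate_genes(iv, genes, flank = 0)
  expect_true(all(hits0$gene_id %in% hits$gene_id))
  expect_setequal(hits0$gene_id, "inside")
})

test_that("high-impact filtering keeps the four quoted classes", {
  rec <- data.frame(
    chrom = "chr01", pos = c(10, 20, 30, 40, 50),
    ref = "A", alt = "T",
    ann = c(
      "T|stop_gained|HIGH|G1|G1|transcript|t1|x|x|x",
      "T|missense_variant|MODERATE|G2|G2|transcript|t2|x|x|x",
      "T|frameshift_variant&stop_gained|HIGH|G3|G3|transcript|t3|x|x|x",
      "T|splice_acceptor_variant|HIGH|G4|G4|transcript|t4|x|x|x",
      NA
    ),
    stringsAsFactors = FALSE
  )
  hi <- filter_high_impact(rec)
  expect_setequal(hi$gene_id, c("G1", "G3", "G4"))
  expect_setequal(hi$effect_class[hi$gene_id == "G3"],
                  c("frameshift", "stop_gained"))
  expect_equal(hi$effect_class[hi$gene_id == "G4"], "splice_site")

  # candidate-gene restriction and AF attachment
  afs <- data.frame(chrom = "chr01", pos = c(10, 30),
                    af_high = c(0.21, 0.9), af_low = c(0.86, 0.1))
  hi2 <- filter_high_impact(rec, candidate_genes = "G1", afs = afs)
  expect_equal(hi2$gene_id, "G1")
  expect_equal(hi2$af_high, 0.21)
  expect_equal(hi2$af_low, 0.86)
})

test_that("annotated VCF round-trip feeds the high-impact filter", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, chrom = c("chr01", "chr01"), pos = c(5, 15),
                ref = "A", alt = "T", ad = c("10,10", "10,10"),
                gt = "0/1",
                info = c("ANN=T|stop_gained|HIGH|G1|G1|t|t1|x|x|x",
                         "ANN=T|synonymous_variant|LOW|G2|G2|t|t2|x|x|x"))
  rec <- read_ann_vcf(path)
  expect_equal(nrow(rec), 2L)
  hi <- filter_high_impact(rec)
  expect_equal(hi$gene_id, "G1")
  expect_equal(hi$effect_class, "stop_gained")
})

test_that("chromosome summaries tally the published interval tables", {
  gsl <- read_interval_table(
    system.file("extdata", "gsl_intervals.tsv", package = "mbsmap"))
  cs <- chromosome_summary(gsl)
  expect_equal(cs$n_intervals[cs$chrom == "chrA09"], 18L)
  expect_equal(attr(cs, "total"), 30L)

  spc <- read_interval_table(
    system.file("extdata", "spc_intervals.tsv", package = "mbsmap"))
  cs2 <- chromosome_summary(spc)
  expect_equal(cs2$n_intervals[cs2$chrom == "chrC08"], 5L)
  expect_equal(attr(cs2, "total"), 15L)

  empty <- chromosome_summary(gsl[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total"), 0L)
})
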