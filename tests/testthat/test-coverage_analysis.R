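test_that("zero-coverage windows are detected and merged", {
  # both pools zero on 1-400, depth elsewhere
  h <- coverage_track("chr01", c(integer(400), rep(1L, 600)), "high")
  l <- coverage_track("chr01", c(integer(400), rep(5L, 600)), "low")
  z <- detect_zcrs(h, l, window = 200L)
  expect_equal(nrow(z), 1L)
  expect_equal(z$start, 1L)
  expect_equal(z$end, 400L)
  expect_equal(z$n_windows, 2L)
})

test_that("a window with reads in either pool is not a ZCR", {
  h <- coverage_track("chr01", integer(400), "high")
  l <- coverage_track("chr01", c(integer(200), rep(5L, 200)), "low")
  z <- detect_zcrs(h, l, window = 200L)
  expect_equal(z$end, 200L)  # only the first window qualifies
  expect_error(
    detect_zcrs(h, coverage_track("chr01", integer(300), "low")),
    "length mismatch")
})

test_that("ZCRs never overlap and never contain a covered base", {
  set.seed(31)
  # mostly-zero tracks with scattered reads: many qualifying windows
  # interrupted at random
  depth_h <- integer(4000)
  depth_l <- integer(4000)
  depth_h[sample.int(4000, 8)] <- rpois(8, 5) + 1L
  depth_l[sample.int(4000, 8)] <- rpois(8, 5) + 1L
  h <- coverage_track("chr01", depth_h, "high")
  l <- coverage_track("chr01", depth_l, "low")
  z <- detect_zcrs(h, l, window = 200L)
  expect_gt(nrow(z), 1L)
  expect_true(all(z$start[-1L] > z$end[-nrow(z)]))
  for (i in seq_len(nrow(z))) {
    span <- z$start[i]:z$end[i]
    expect_true(all(depth_h[span] == 0L & depth_l[span] == 0L))
    expect_equal((z$end[i] - z$start[i] + 1L) %% 200L, 0L)
  }
})

test_that("gene mean coverage averages the gene body", {
  tr <- coverage_track("chr01", rep(12L, 1000), "high")
  gene <- data.frame(gene_id = "g1", chrom = "chr01",
                     start = 101L, end = 200L, stringsAsFactors = FALSE)
  expect_equal(gene_mean_coverage(tr, gene), 12)
  half <- coverage_track("chr01", c(integer(500), rep(20L, 500)), "high")
  gene2 <- data.frame(gene_id = "g2", chrom = "chr01",
                      start = 401L, end = 600L, stringsAsFactors = FALSE)
  expect_equal(gene_mean_coverage(half, gene2), 10)
  gene3 <- data.frame(gene_id = "g3", chrom = "chr01",
                      start = 900L, end = 1100L, stringsAsFactors = FALSE)
  expect_error(gene_mean_coverage(tr, gene3), "outside")
})

test_that("PAV calling applies the mincov gate and ranks by ratio", {
  genes <- data.frame(
    gene_id = c("depleted", "covered", "weak"),
    chrom = "chr01",
    start = c(101L, 1101L, 2101L),
    end = c(600L, 1600L, 2600L),
    strand = "+", annotation = "", stringsAsFactors = FALSE
  )
  depth_h <- rep(30L, 3000)
  depth_h[101:600] <- 2L     # depleted in high pool, ratio 15
  depth_l <- rep(30L, 3000)
  depth_h[2101:2600] <- 12L  # min raw 12 >= mincov -> no call
  ch <- list(chr01 = coverage_track("chr01", depth_h, "high"))
  cl <- list(chr01 = coverage_track("chr01", depth_l, "low"))
  pav <- detect_pavs(genes, ch, cl, mincov = 10)
  expect_equal(pav$gene_id, "depleted")
  expect_equal(pav$direction, "high")
  # normalization divides each gene mean by its pool's genome-wide mean
  expect_equal(pav$ratio, (30 / mean(depth_l)) / (2 / mean(depth_h)))
})

test_that("PAV detection is pool-symmetric up to the direction label", {
  set.seed(32)
  depth_a <- rpois(3000, 25)
  depth_b <- rpois(3000, 25)
  depth_b[501:1000] <- rpois(500, 2)
  genes <- data.frame(gene_id = "g", chrom = "chr01",
                      start = 501L, end = 1000L, strand = "+",
                      annotation = "", stringsAsFactors = FALSE)
  a <- list(chr01 = coverage_track("chr01", depth_a, "a"))
  b <- list(chr01 = coverage_track("chr01", depth_b, "b"))
  fwd <- detect_pavs(genes, a, b)
  rev <- detect_pavs(genes, b, a)
  expect_equal(fwd$ratio, rev$ratio)
  expect_equal(fwd$direction, "low")
  expect_equal(rev$direction, "high")
})

test_that("genes with no coverage in either pool are not called", {
  genes <- data.frame(gene_id = "g", chrom = "chr01",
                      start = 101L, end = 200L, strand = "+",
                      annotation = "", stringsAsFactors = FALSE)
  z <- integer(300)
  a <- list(chr01 = coverage_track("chr01", z, "a"))
  expect_equal(nrow(detect_pavs(genes, a, a)), 0L)
})

test_that("simulated structural variants are recovered", {
  sim <- simulate_f2(sv_fixture_config(), coverage = TRUE)
  dels <- sim$config$deletions

  # shared deletion -> ZCR with exact boundaries at window resolution
  z <- detect_zcrs_genome(sim$coverage$high, sim$coverage$low)
  shared <- dels[dels$carrier == "both", ]
  expect_equal(nrow(z), 1L)
  expect_equal(z$start, shared$start)
  expect_equal(z$end, shared$end)

  # single-parent deletion under opposite selection -> its genes are
  # top-ranked PAVs with a ~3x normalized contrast
  pav <- detect_pavs(sim$genes, sim$coverage$high, sim$coverage$low)
  p1_del <- dels[dels$carrier == "p1", ]
  del_genes <- sim$genes$gene_id[sim$genes$chrom == p1_del$chrom &
                                   sim$genes$start >= p1_del$start &
                                   sim$genes$end <= p1_del$end]
  expect_true(length(del_genes) >= 2L)
  expect_true(all(del_genes %in% pav$gene_id))
  expect_true(all(match(del_genes, pav$gene_id) <= 10L))
  hits <- pav[pav$gene_id %in% del_genes, ]
  expect_true(all(hits$direction == "low"))  # deletion rides the low pool
  expect_true(all(hits$ratio >= 2 & hits$ratio <= 4))

  # depleted-pool gene coverage sits near the present-haplotype share
  sites <- sim$truth$sites
  for (g in del_genes) {
    row <- sim$genes[sim$genes$gene_id == g, ]
    raw_low <- gene_mean_coverage(sim$coverage$low$chr01, row)
    frac <- mean(sites$present_frac_low[sites$pos >= p1_del$start &
                                          sites$pos <= p1_del$end])
    expect_equal(raw_low, sim$config$mean_depth * frac, tolerance = 0.2)
  }
})
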