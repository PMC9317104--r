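small_cfg <- function(seed = 3, ...) {
  sim_config(n_chromosomes = 1L, chrom_length = 2e6, n_f2 = 400L,
             mean_depth = 50, seed = seed, ...)
}

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_f2(small_cfg(), coverage = FALSE)
  b <- simulate_f2(small_cfg(), coverage = FALSE)
  expect_identical(a$pools, b$pools)
  expect_identical(a$parents, b$parents)
  expect_identical(a$truth$sites, b$truth$sites)
  c <- simulate_f2(small_cfg(seed = 4), coverage = FALSE)
  expect_false(identical(a$pools$high, c$pools$high))
})

# The phenotype effect acts on the parent-2 allele; the ALT allele at
# any one site belongs to a random parent, so truth frequencies are
# re-oriented to the parent-2 allele before comparing with selection
# expectations.
p2_af <- function(sites, i, pool) {
  af <- sites[[paste0("af_", pool)]][i]
  ifelse(sites$alt_parent[i] == "p2", af, 1 - af)
}

test_that("strong selection drives the causal-site pool frequencies apart", {
  sim <- simulate_f2(small_cfg(), coverage = FALSE)
  ts <- sim$truth$sites
  i <- which.min(abs(ts$pos - sim$config$causal_loci$pos))
  expect_gt(p2_af(ts, i, "high"), 0.8)
  expect_lt(p2_af(ts, i, "low"), 0.2)
})

test_that("sites unlinked to the causal locus stay near 0.5", {
  # second chromosome carries no causal locus: free recombination
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 1e6,
                    n_f2 = 400L, seed = 12,
                    causal_loci = data.frame(chrom = "chr01", pos = 5e5,
                                             effect = 1))
  sim <- simulate_f2(cfg, coverage = FALSE)
  ts <- sim$truth$sites[sim$truth$sites$chrom == "chr02", ]
  pool_n <- length(sim$truth$high_idx)
  se <- sqrt(0.25 / (2 * pool_n))
  expect_lt(mean(abs(ts$af_high - 0.5) > 3 * se), 0.05)
  expect_lt(mean(abs(ts$af_low - 0.5) > 3 * se), 0.05)
})

test_that("a deletion carried by both parents zeroes both pools exactly", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 5e5, n_f2 = 100L,
                    seed = 5,
                    deletions = data.frame(chrom = "chr01", start = 100001L,
                                           end = 110000L, carrier = "both"))
  sim <- simulate_f2(cfg, coverage = TRUE)
  span <- 100001:110000
  expect_true(all(sim$coverage$high$chr01$depth[span] == 0L))
  expect_true(all(sim$coverage$low$chr01$depth[span] == 0L))
  expect_gt(mean(sim$coverage$high$chr01$depth[-span]), 0)
})

test_that("expected_pool_af has the right limits and matches enumeration", {
  q0 <- causal_pool_af(0.05, 1, 0.5, "high")
  expect_equal(expected_pool_af(0, causal_af = q0), q0)
  expect_equal(expected_pool_af(1e6, causal_af = q0), 0.5,
               tolerance = 1e-12)
  expect_equal(causal_pool_af(0.05, 1, 0.5, "low"), 1 - q0,
               tolerance = 1e-6)

  # enumeration oracle at 10 cM: sum over gamete classes
  # (causal allele c, marker allele m) with P(c) from the pool
  # frequency and P(m | c) from the Haldane recombination fraction
  r <- (1 - exp(-2 * 10 / 100)) / 2
  classes <- expand.grid(c = 0:1, m = 0:1)
  p_class <- ifelse(classes$c == 1, 0.9, 0.1) *
    ifelse(classes$m == classes$c, 1 - r, r)
  oracle <- sum(p_class * classes$m)
  expect_equal(expected_pool_af(10, causal_af = 0.9), oracle)
})

test_that("closed-form causal pool frequency matches the selection truth", {
  # average the simulator's realized causal-site frequency over seeds
  cfgs <- lapply(1:6, function(s) small_cfg(seed = 100 + s))
  obs <- vapply(cfgs, function(cfg) {
    sim <- simulate_f2(cfg, coverage = FALSE)
    ts <- sim$truth$sites
    i <- which.min(abs(ts$pos - cfg$causal_loci$pos))
    p2_af(ts, i, "high")
  }, numeric(1L))
  expect_equal(mean(obs), causal_pool_af(0.05, 1, 0.5, "high"),
               tolerance = 0.05)
})

test_that("a written simulation round-trips through the readers", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 2e5, n_f2 = 60L,
                    seed = 9,
                    deletions = data.frame(chrom = "chr01", start = 50001L,
                                           end = 60000L, carrier = "p2"))
  sim <- simulate_f2(cfg, coverage = TRUE)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)

  p1 <- read_vcf(paths[["p1"]], "P1")
  expect_equal(p1$pos, sim$parents$p1$pos)
  expect_equal(p1$ref_count, sim$parents$p1$ref_count)
  expect_equal(p1$alt_count, sim$parents$p1$alt_count)
  expect_equal(p1$genotype, sim$parents$p1$genotype)

  high <- read_vcf(paths[["pool_high"]], "POOL_HIGH")
  expect_equal(high$alt_count, sim$pools$high$alt_count)

  cov <- read_coverage(paths[["coverage_low"]],
                       chrom_lengths = sim$chrom_lengths, pool_id = "low")
  expect_equal(cov$chr01$depth, sim$coverage$low$chr01$depth)

  genes <- read_gff3(paths[["genes"]])
  expect_equal(genes, sim$genes)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$sites), nrow(sim$truth$sites))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_f2 = 10L, tail_low = 0.01), "tail fraction")
  expect_error(sim_config(tail_low = 0.6))
  expect_error(sim_config(causal_loci = data.frame(chrom = "chr01",
                                                   pos = 5e7, effect = 1)))
})
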