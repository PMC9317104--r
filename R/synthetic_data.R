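#' Configuration for a simulated mapping-by-sequencing experiment
#'
#' Bundles every parameter of the synthetic F2 cross. The defaults
#' describe the reference study design at desk scale: one 20 Mbp
#' chromosome with one SNV per 2 kbp segregating from two fully
#' homozygous parents, an F2 of 1000 plants, 5% phenotype tails pooled
#' on each side, 50x mean pool depth, and a single major additive locus
#' (effect 1 phenotypic unit per allele against residual s.d. 0.5,
#' i.e. a heritability of 2/3).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp (recycled).
#' @param snv_density Expected SNVs per bp (default 1/2000).
#' @param n_f2 F2 population size.
#' @param tail_low,tail_high Fractions of the population selected into
#'   the low/high pools (each in (0, 0.5)).
#' @param causal_loci Data.frame with columns `chrom`, `pos`, `effect`;
#'   `effect` is the phenotype shift per allele inherited from parent 2.
#' @param residual_sd Standard deviation of the Gaussian environmental
#'   noise added to the genetic value.
#' @param mean_depth Mean sequencing depth per pool (reads per site,
#'   Poisson).
#' @param cm_per_mb Recombination rate in centimorgan per megabase
#'   (Haldane model, no interference).
#' @param deletions Optional data.frame with columns `chrom`, `start`,
#'   `end`, `carrier` (`"p1"`, `"p2"` or `"both"`); carrier haplotypes
#'   contribute no reads inside the region.
#' @param error_rate Per-read allele flip probability (default 0).
#' @param epistasis Optional data.frame with columns `locus1`, `locus2`
#'   (row indices into `causal_loci`) and `effect`, adding
#'   `effect * (g1 - 1) * (g2 - 1)` to the phenotype.
#' @param seed Random seed making the simulation reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 20e6,
                       snv_density = 1 / 2000,
                       n_f2 = 1000L,
                       tail_low = 0.05,
                       tail_high = 0.05,
                       causal_loci = NULL,
                       residual_sd = 0.5,
                       mean_depth = 50,
                       cm_per_mb = 2,
                       deletions = NULL,
                       error_rate = 0,
                       epistasis = NULL,
                       seed = 1L) {
  chrom_length <- rep_len(as.numeric(chrom_length), n_chromosomes)
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  names(chrom_length) <- chroms
  if (is.null(causal_loci)) {
    causal_loci <- data.frame(chrom = chroms[1L],
                              pos = round(chrom_length[1L] / 2),
                              effect = 1, stringsAsFactors = FALSE)
  }
  cfg <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    snv_density = snv_density, n_f2 = as.integer(n_f2),
    tail_low = tail_low, tail_high = tail_high,
    causal_loci = causal_loci, residual_sd = residual_sd,
    mean_depth = mean_depth, cm_per_mb = cm_per_mb,
    deletions = deletions, error_rate = error_rate,
    epistasis = epistasis, seed = as.integer(seed)
  )
  stopifnot(
    cfg$tail_low > 0, cfg$tail_low < 0.5,
    cfg$tail_high > 0, cfg$tail_high < 0.5,
    cfg$mean_depth > 0,
    all(cfg$causal_loci$chrom %in% chroms),
    all(cfg$causal_loci$pos >= 1),
    all(cfg$causal_loci$pos <= chrom_length[cfg$causal_loci$chrom])
  )
  if (floor(cfg$tail_low * cfg$n_f2) < 1 ||
      floor(cfg$tail_high * cfg$n_f2) < 1) {
    stop("tail fraction selects no individuals at n_f2 = ", cfg$n_f2)
  }
  if (!is.null(deletions)) {
    stopifnot(all(deletions$carrier %in% c("p1", "p2", "both")),
              all(deletions$chrom %in% chroms),
              all(deletions$start >= 1),
              all(deletions$end <= chrom_length[deletions$chrom]))
  }
  structure(cfg, class = "sim_config")
}

# Origin of a gamete at given positions: 0 = parent-1 haplotype,
# 1 = parent-2. A gamete is a start phase plus sorted crossover points.
gamete_origin <- function(gamete, positions) {
  (gamete$phase + findInterval(positions, gamete$breaks)) %% 2L
}

# Draw one gamete from the F1: Poisson(#morgans) crossovers placed
# uniformly (Haldane), random start phase.
draw_gamete <- function(len_bp, cm_per_mb) {
  morgans <- len_bp * cm_per_mb / 1e8
  n_x <- stats::rpois(1L, morgans)
  list(phase = sample(0:1, 1L),
       breaks = sort(stats::runif(n_x, min = 1, max = len_bp)))
}

#' Simulate a complete mapping-by-sequencing experiment
#'
#' Generates parents, an F2 population, phenotype-tail pools, pool read
#' counts and (optionally) per-base coverage tracks, together with a
#' truth table for every downstream check:
#'
#' 1. SNVs are placed uniformly at the configured density; at each
#'    site one parent (chosen at random) is homozygous for the
#'    alternate allele, the other matches the reference.
#' 2. Each F2 individual receives two independent F1 gametes with
#'    Haldane crossovers at `cm_per_mb`.
#' 3. Phenotype = sum of additive effects over the causal genotypes
#'    (+ optional epistasis) + Gaussian noise.
#' 4. Pools are the phenotype tails.
#' 5. Pool read counts per site are binomial draws at
#'    Poisson-distributed depth from the pool's true allele frequency.
#' 6. Haplotypes carrying a deletion contribute no reads inside it;
#'    shared deletions therefore give exactly zero coverage.
#'
#' Parent variant tables include homozygous-reference records (with
#' `alt_count = 0`), mirroring an all-sites caller, so that
#' [reconstitute_f1()] can sum both parents' reads at every site.
#'
#' @param config A [sim_config()] object.
#' @param coverage Generate per-base coverage tracks (`TRUE`, the
#'   default). Turn off when only variant tables are needed — per-base
#'   tracks dominate memory and runtime for long chromosomes.
#' @return An `mbs_simulation` list with elements `config`,
#'   `chrom_lengths`, `parents` (`$p1`, `$p2` variant tables), `pools`
#'   (`$high`, `$low`), `coverage` (`$high`, `$low` track lists or
#'   `NULL`), `genes` (toy gene models tiled along each chromosome)
#'   and `truth` (per-site parental alleles and true pool allele
#'   frequencies, causal loci, deletions, pool member indices).
#' @export
simulate_f2 <- function(config, coverage = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_length)

  # --- variant sites ---------------------------------------------------
  sites <- do.call(rbind, lapply(chroms, function(chr) {
    len <- config$chrom_length[[chr]]
    n <- max(1L, round(len * config$snv_density))
    pos <- sort(sample.int(len, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
               alt_parent = sample(c("p1", "p2"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  # --- F2 gametes and phenotypes --------------------------------------
  gametes <- lapply(seq_len(config$n_f2), function(i) {
    lapply(chroms, function(chr) {
      list(draw_gamete(config$chrom_length[[chr]], config$cm_per_mb),
           draw_gamete(config$chrom_length[[chr]], config$cm_per_mb))
    })
  })
  for (i in seq_along(gametes)) names(gametes[[i]]) <- chroms

  causal <- config$causal_loci
  causal_geno <- vapply(seq_len(config$n_f2), function(i) {
    vapply(seq_len(nrow(causal)), function(k) {
      pair <- gametes[[i]][[causal$chrom[k]]]
      gamete_origin(pair[[1L]], causal$pos[k]) +
        gamete_origin(pair[[2L]], causal$pos[k])
    }, numeric(1L))
  }, numeric(nrow(causal)))
  causal_geno <- matrix(causal_geno, nrow = nrow(causal))

  genetic <- colSums(causal$effect * (causal_geno - 1))
  if (!is.null(config$epistasis)) {
    for (k in seq_len(nrow(config$epistasis))) {
      e <- config$epistasis[k, ]
      genetic <- genetic + e$effect *
        (causal_geno[e$locus1, ] - 1) * (causal_geno[e$locus2, ] - 1)
    }
  }
  phenotype <- genetic + stats::rnorm(config$n_f2, sd = config$residual_sd)

  ord <- order(phenotype)
  low_idx <- ord[seq_len(floor(config$tail_low * config$n_f2))]
  high_idx <- ord[seq(config$n_f2 - floor(config$tail_high * config$n_f2) + 1L,
                      config$n_f2)]

  # --- pool haplotype origins at every site ---------------------------
  pool_origins <- function(members, chr, positions) {
    # matrix: 2*length(members) haplotypes x length(positions); 1 = P2
    do.call(rbind, lapply(members, function(i) {
      pair <- gametes[[i]][[chr]]
      rbind(gamete_origin(pair[[1L]], positions),
            gamete_origin(pair[[2L]], positions))
    }))
  }

  dels <- config$deletions
  deleted_mask <- function(origins, chr, positions, carrier_pool) {
    # logical matrix same shape as origins: TRUE where haplotype lacks
    # the region (carrier-origin haplotype inside a deletion)
    del <- matrix(FALSE, nrow(origins), ncol(origins))
    if (is.null(dels)) return(del)
    for (k in which(dels$chrom == chr)) {
      inside <- positions >= dels$start[k] & positions <= dels$end[k]
      if (!any(inside)) next
      hit <- switch(dels$carrier[k],
                    p1 = origins[, inside, drop = FALSE] == 0L,
                    p2 = origins[, inside, drop = FALSE] == 1L,
                    both = matrix(TRUE, nrow(origins), sum(inside)))
      del[, inside] <- del[, inside, drop = FALSE] | hit
    }
    del
  }

  pool_counts <- function(members) {
    res <- lapply(chroms, function(chr) {
      sub <- sites[sites$chrom == chr, , drop = FALSE]
      org <- pool_origins(members, chr, sub$pos)
      del <- deleted_mask(org, chr, sub$pos)
      n_hap <- nrow(org)
      # alt carried by P2-origin haplotypes where alt_parent == "p2",
      # by P1-origin haplotypes otherwise
      is_alt <- sweep(org == 1L, 2L, sub$alt_parent == "p2", `==`)
      present <- colSums(!del)
      alt_present <- colSums(is_alt & !del)
      af_present <- ifelse(present > 0, alt_present / present, 0)
      af_true <- colMeans(is_alt)
      depth <- stats::rpois(nrow(sub),
                            config$mean_depth * present / n_hap)
      p_read <- af_present * (1 - config$error_rate) +
        (1 - af_present) * config$error_rate
      alt_count <- stats::rbinom(nrow(sub), depth, p_read)
      list(sub = sub, depth = depth, alt_count = alt_count,
           af_true = af_true, present_frac = present / n_hap)
    })
    names(res) <- chroms
    res
  }

  counts_to_variants <- function(cnt) {
    out <- do.call(rbind, lapply(cnt, function(x) {
      ref_count <- x$depth - x$alt_count
      genotype <- ifelse(x$depth == 0L, "missing",
                         ifelse(x$alt_count == 0L, "hom_ref",
                                ifelse(ref_count == 0L, "hom_alt", "het")))
      data.frame(chrom = x$sub$chrom, pos = x$sub$pos, ref = x$sub$ref,
                 alt = x$sub$alt, ref_count = ref_count,
                 alt_count = x$alt_count, filter_status = "PASS",
                 genotype = genotype, type = "snv",
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }

  cnt_high <- pool_counts(high_idx)
  cnt_low <- pool_counts(low_idx)

  # --- parent variant tables ------------------------------------------
  parent_variants <- function(parent) {
    out <- do.call(rbind, lapply(chroms, function(chr) {
      sub <- sites[sites$chrom == chr, , drop = FALSE]
      depth <- stats::rpois(nrow(sub), config$mean_depth)
      if (!is.null(dels)) {
        for (k in which(dels$chrom == chr &
                          dels$carrier %in% c(parent, "both"))) {
          depth[sub$pos >= dels$start[k] & sub$pos <= dels$end[k]] <- 0L
        }
      }
      carries_alt <- sub$alt_parent == parent
      alt_count <- ifelse(carries_alt, depth, 0L)
      ref_count <- depth - alt_count
      genotype <- ifelse(depth == 0L, "missing",
                         ifelse(carries_alt, "hom_alt", "hom_ref"))
      data.frame(chrom = chr, pos = sub$pos, ref = sub$ref,
                 alt = sub$alt, ref_count = ref_count,
                 alt_count = alt_count, filter_status = "PASS",
                 genotype = genotype, type = "snv",
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }

  # --- coverage tracks -------------------------------------------------
  make_coverage <- function(members, pool_id) {
    tracks <- lapply(chroms, function(chr) {
      len <- config$chrom_length[[chr]]
      lambda <- rep(config$mean_depth, len)
      if (!is.null(dels)) {
        for (k in which(dels$chrom == chr)) {
          span <- dels$start[k]:dels$end[k]
          if (dels$carrier[k] == "both") {
            lambda[span] <- 0
          } else {
            # present fraction evaluated at 200 bp segment midpoints;
            # crossovers inside a deletion are rare enough for that
            grid <- seq(dels$start[k], dels$end[k], by = 200L)
            mids <- pmin(grid + 99L, dels$end[k])
            org <- pool_origins(members, chr, mids)
            carrier_org <- if (dels$carrier[k] == "p1") 0L else 1L
            frac_present <- colMeans(org != carrier_org)
            seg <- findInterval(span, grid)
            lambda[span] <- pmin(lambda[span],
                                 config$mean_depth * frac_present[seg])
          }
        }
      }
      coverage_track(chr, stats::rpois(len, lambda), pool_id)
    })
    names(tracks) <- chroms
    tracks
  }

  # --- toy gene models -------------------------------------------------
  genes <- do.call(rbind, lapply(chroms, function(chr) {
    len <- config$chrom_length[[chr]]
    starts <- seq(5001, len - 2000, by = 20000)
    data.frame(
      gene_id = sprintf("%s_g%05d", chr, seq_along(starts)),
      chrom = chr, start = starts, end = starts + 1999,
      strand = "+", annotation = "", stringsAsFactors = FALSE
    )
  }))
  rownames(genes) <- NULL

  truth_sites <- sites
  truth_sites$af_high <- unlist(lapply(cnt_high, `[[`, "af_true"))
  truth_sites$af_low <- unlist(lapply(cnt_low, `[[`, "af_true"))
  truth_sites$present_frac_high <-
    unlist(lapply(cnt_high, `[[`, "present_frac"))
  truth_sites$present_frac_low <-
    unlist(lapply(cnt_low, `[[`, "present_frac"))
  rownames(truth_sites) <- NULL

  structure(list(
    config = config,
    chrom_lengths = config$chrom_length,
    parents = list(p1 = parent_variants("p1"), p2 = parent_variants("p2")),
    pools = list(high = counts_to_variants(cnt_high),
                 low = counts_to_variants(cnt_low)),
    coverage = if (coverage) {
      list(high = make_coverage(high_idx, "high"),
           low = make_coverage(low_idx, "low"))
    },
    genes = genes,
    truth = list(sites = truth_sites,
                 causal_loci = causal,
                 deletions = dels,
                 phenotype = phenotype,
                 high_idx = high_idx, low_idx = low_idx)
  ), class = "mbs_simulation")
}

#' @export
print.mbs_simulation <- function(x, ...) {
  cat(sprintf(
    "<mbs_simulation> %d chromosome(s), %d SNVs, F2 n = %d, pools %d/%d\n",
    x$config$n_chromosomes, nrow(x$truth$sites), x$config$n_f2,
    length(x$truth$high_idx), length(x$truth$low_idx)))
  invisible(x)
}

#' Write a simulated experiment to disk in standard formats
#'
#' Emits the parental and pool VCFs, per-pool coverage TSVs, gene
#' models as GFF3 and the truth table as JSON, all in the dialects
#' that the package's readers consume.
#'
#' @param sim An `mbs_simulation` from [simulate_f2()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- sim$chrom_lengths
  paths <- c(
    p1 = file.path(dir, "parent1.vcf"),
    p2 = file.path(dir, "parent2.vcf"),
    pool_high = file.path(dir, "pool_high.vcf"),
    pool_low = file.path(dir, "pool_low.vcf"),
    coverage_high = file.path(dir, "coverage_high.tsv"),
    coverage_low = file.path(dir, "coverage_low.tsv"),
    genes = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$parents$p1, paths[["p1"]], "P1", contigs)
  write_vcf(sim$parents$p2, paths[["p2"]], "P2", contigs)
  write_vcf(sim$pools$high, paths[["pool_high"]], "POOL_HIGH", contigs)
  write_vcf(sim$pools$low, paths[["pool_low"]], "POOL_LOW", contigs)
  if (!is.null(sim$coverage)) {
    write_coverage(sim$coverage$high, paths[["coverage_high"]])
    write_coverage(sim$coverage$low, paths[["coverage_low"]])
  } else {
    paths <- paths[!names(paths) %in% c("coverage_high", "coverage_low")]
  }
  write_gff3(sim$genes, paths[["genes"]])
  jsonlite::write_json(
    list(sites = sim$truth$sites,
         causal_loci = sim$truth$causal_loci,
         deletions = sim$truth$deletions,
         high_idx = sim$truth$high_idx,
         low_idx = sim$truth$low_idx,
         chrom_lengths = as.list(sim$chrom_lengths)),
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' Expected causal-locus allele frequency in a selected pool
#'
#' Closed form for the frequency of the parent-2 allele of a single
#' additive locus among individuals selected from a phenotype tail.
#' The F2 genotype is Binomial(2, 1/2); the phenotype is
#' `effect * (g - 1)` plus Gaussian noise; the selection threshold is
#' the population quantile at the tail fraction.
#'
#' @param tail_fraction Selected fraction of the population.
#' @param effect Additive effect per parent-2 allele.
#' @param residual_sd Residual (environmental) standard deviation.
#' @param pool `"high"` (upper tail) or `"low"`.
#' @return Expected allele frequency in the selected pool.
#' @export
causal_pool_af <- function(tail_fraction = 0.05, effect = 1,
                           residual_sd = 0.5, pool = c("high", "low")) {
  pool <- match.arg(pool)
  p_g <- c(0.25, 0.5, 0.25)
  mu_g <- effect * (0:2 - 1)
  upper <- pool == "high"
  tail_prob <- function(t) {
    sum(p_g * stats::pnorm(t, mean = mu_g, sd = residual_sd,
                           lower.tail = !upper))
  }
  span <- max(abs(mu_g)) + 10 * residual_sd
  t <- stats::uniroot(function(t) tail_prob(t) - tail_fraction,
                      lower = -span, upper = span, tol = 1e-10)$root
  w <- p_g * stats::pnorm(t, mean = mu_g, sd = residual_sd,
                          lower.tail = !upper)
  sum(w * (0:2)) / (2 * sum(w))
}

#' Expected pool allele frequency at a linked marker
#'
#' Combines the causal-locus pool frequency with the Haldane
#' recombination fraction `r = (1 - exp(-2 d / 100)) / 2` at genetic
#' distance `d` (in cM): a marker allele in coupling with the causal
#' parent-2 allele is expected at frequency
#' `q (1 - r) + (1 - q) r` in the pool. At distance 0 this is the
#' causal frequency itself; with free recombination it decays to 0.5.
#'
#' @param distance_cm Genetic distance between marker and causal locus
#'   in centimorgan.
#' @param tail_fraction,effect,residual_sd Selection model passed to
#'   [causal_pool_af()] (ignored when `causal_af` is given).
#' @param pool `"high"` or `"low"`.
#' @param causal_af Optional known causal-locus pool frequency,
#'   bypassing the closed-form selection model.
#' @return Expected marker allele frequency in the pool.
#' @export
expected_pool_af <- function(distance_cm, tail_fraction = 0.05,
                             effect = 1, residual_sd = 0.5,
                             pool = c("high", "low"), causal_af = NULL) {
  stopifnot(all(distance_cm >= 0))
  pool <- match.arg(pool)
  if (is.null(causal_af)) {
    causal_af <- causal_pool_af(tail_fraction, effect, residual_sd, pool)
  }
  r <- (1 - exp(-2 * distance_cm / 100)) / 2
  causal_af * (1 - r) + (1 - causal_af) * r
}
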