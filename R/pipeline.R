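#' Detect zero-coverage regions across all chromosomes
#'
#' Applies [detect_zcrs()] to every chromosome present in both pools'
#' track lists and binds the results.
#'
#' @param cov_high,cov_low Named lists of [coverage_track()] objects.
#' @param window Window size in bp (default 200).
#' @return Combined ZCR data.frame.
#' @export
detect_zcrs_genome <- function(cov_high, cov_low, window = 200L) {
  chroms <- intersect(names(cov_high), names(cov_low))
  out <- do.call(rbind, lapply(chroms, function(chr) {
    detect_zcrs(cov_high[[chr]], cov_low[[chr]], window)
  }))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the full mapping-by-sequencing pipeline on one experiment
#'
#' Chains every stage: gold-standard construction from the parents,
#' pool filtering against it, the pool join with delta allele
#' frequencies, the Fisher-exact dARC calls, zero-coverage detection
#' (when coverage tracks are available) and interval detection.
#'
#' @param p1,p2 Parental variant tables from [read_vcf()] (or a
#'   simulation).
#' @param pool_high,pool_low Pool variant tables.
#' @param cov_high,cov_low Optional named track lists for ZCR
#'   detection.
#' @param alpha,correction dARC calling parameters, see [call_darcs()].
#' @param min_darc_cutoff,trait_label Interval reporting parameters,
#'   see [rank_and_threshold()].
#' @param ... Further interval-rule parameters passed to
#'   [detect_intervals()].
#' @return List with elements `gold`, `joined`, `darcs`, `zcrs`,
#'   `intervals`.
#' @export
run_mbs_pipeline <- function(p1, p2, pool_high, pool_low,
                             cov_high = NULL, cov_low = NULL,
                             alpha = 0.05,
                             correction = "benjamini-hochberg",
                             min_darc_cutoff = 4L,
                             trait_label = "TRAIT", ...) {
  gold <- build_gold_standard(p1, p2)
  fh <- filter_pool_variants(pool_high, gold)
  fl <- filter_pool_variants(pool_low, gold)
  joined <- join_pools(fh, fl)
  darcs <- call_darcs(joined, alpha = alpha, method = correction)
  zcrs <- if (!is.null(cov_high) && !is.null(cov_low)) {
    detect_zcrs_genome(cov_high, cov_low)
  }
  intervals <- detect_intervals(darcs, zcrs,
                                min_darc_cutoff = min_darc_cutoff,
                                trait_label = trait_label, ...)
  list(gold = gold, joined = joined, darcs = darcs, zcrs = zcrs,
       intervals = intervals)
}

#' Run the pipeline directly on a simulated experiment
#'
#' Convenience wrapper unpacking an `mbs_simulation` into
#' [run_mbs_pipeline()].
#'
#' @param sim An `mbs_simulation` from [simulate_f2()].
#' @param ... Passed on to [run_mbs_pipeline()].
#' @return See [run_mbs_pipeline()].
#' @export
run_mbs_pipeline_sim <- function(sim, ...) {
  run_mbs_pipeline(
    sim$parents$p1, sim$parents$p2,
    sim$pools$high, sim$pools$low,
    cov_high = sim$coverage$high, cov_low = sim$coverage$low,
    ...
  )
}
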