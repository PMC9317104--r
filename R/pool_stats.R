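#' Median per-site read depth of a pool
#'
#' @param variants Data.frame with `ref_count` and `alt_count` columns.
#' @return Median of `ref_count + alt_count` (even-length inputs use
#'   the usual mean-of-central-pair convention).
#' @export
pool_median_coverage <- function(variants) {
  if (nrow(variants) == 0L) stop("no variants: median coverage undefined")
  stats::median(variants$ref_count + variants$alt_count)
}

#' Filter a pool's variants against the gold standard and depth bounds
#'
#' Keeps biallelic SNVs at gold-standard positions whose total depth
#' lies within `[lo_factor * M, hi_factor * M]` (inclusive), where `M`
#' is the pool's median depth over gold-standard positions. The
#' depth band removes sites in collapsed repeats (too deep) and sites
#' with unreliable frequency estimates (too shallow) relative to the
#' pool's own sequencing depth.
#'
#' @param pool Data.frame from [read_vcf()] for one pool.
#' @param gold A `gold_standard` object (or any data.frame with
#'   `chrom` and `pos`).
#' @param lo_factor,hi_factor Multiples of the median depth bounding
#'   the band (defaults 0.75 and 1.5).
#' @return The retained rows, with the median used stored in the
#'   `median_coverage` attribute.
#' @export
filter_pool_variants <- function(pool, gold, lo_factor = 0.75,
                                 hi_factor = 1.5) {
  in_gold <- paste(pool$chrom, pool$pos) %in% paste(gold$chrom, gold$pos)
  snv <- pool$type == "snv"
  candidates <- pool[in_gold & snv, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    attr(candidates, "median_coverage") <- NA_real_
    return(candidates)
  }
  m <- pool_median_coverage(candidates)
  depth <- candidates$ref_count + candidates$alt_count
  out <- candidates[depth >= lo_factor * m & depth <= hi_factor * m, ,
                    drop = FALSE]
  rownames(out) <- NULL
  attr(out, "median_coverage") <- m
  out
}

#' Delta allele frequency between two pools
#'
#' The dAF of a variant is the absolute difference between its
#' alternate-allele read frequencies in the high- and low-phenotype
#' pools; it is symmetric in its arguments and lies in \[0, 1\].
#'
#' @param af_high,af_low Allele frequencies in \[0, 1\] (vectorized).
#' @return `|af_high - af_low|`.
#' @export
delta_af <- function(af_high, af_low) {
  stopifnot(all(af_high >= 0 & af_high <= 1),
            all(af_low >= 0 & af_low <= 1))
  abs(af_high - af_low)
}

#' Join the two filtered pools into allele-frequency records
#'
#' Inner join on position; only sites where both pools report the same
#' single alternate allele are kept, so every record is a clean
#' biallelic contrast. Records with mismatched ALT alleles between the
#' pools are excluded and counted in the `n_alt_mismatch` attribute.
#'
#' @param high,low Filtered pool tables (see [filter_pool_variants()]).
#' @return Data.frame sorted by `(chrom, pos)` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `ref_high`, `alt_high`, `ref_low`, `alt_low`,
#'   `af_high`, `af_low`, `daf`.
#' @export
join_pools <- function(high, low) {
  h <- data.frame(chrom = high$chrom, pos = high$pos, ref = high$ref,
                  alt = high$alt, ref_high = high$ref_count,
                  alt_high = high$alt_count, stringsAsFactors = FALSE)
  l <- data.frame(chrom = low$chrom, pos = low$pos, alt_l = low$alt,
                  ref_low = low$ref_count, alt_low = low$alt_count,
                  stringsAsFactors = FALSE)
  m <- merge(h, l, by = c("chrom", "pos"))
  mismatch <- m$alt != m$alt_l
  n_mismatch <- sum(mismatch)
  m <- m[!mismatch, , drop = FALSE]
  m$alt_l <- NULL
  m$af_high <- m$alt_high / (m$ref_high + m$alt_high)
  m$af_low <- m$alt_low / (m$ref_low + m$alt_low)
  m$daf <- delta_af(m$af_high, m$af_low)
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  m <- m[!duplicated(paste(m$chrom, m$pos)), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "n_alt_mismatch") <- n_mismatch
  m
}
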