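#' Filter one parent's variants for gold-standard candidacy
#'
#' Keeps homozygous-alternate, biallelic SNVs whose total read depth
#' lies within a coverage band. The band guards against copy-number
#' artifacts: sites below `min_cov` are unreliably genotyped, sites
#' above `max_cov` (about twice the modal depth of a typical parental
#' run) are likely collapsed repeats.
#'
#' When the caller's genotype is missing, homozygosity falls back to an
#' alternate-read fraction of at least `hom_af_fallback`.
#'
#' @param variants Data.frame from [read_vcf()] for one parent.
#' @param min_cov,max_cov Inclusive total-depth bounds (defaults 10 and
#'   60 reads).
#' @param hom_af_fallback Alternate-allele read fraction treated as
#'   homozygous when the genotype label is `"missing"`.
#' @return The retained rows of `variants`.
#' @export
filter_parental_variants <- function(variants, min_cov = 10, max_cov = 60,
                                     hom_af_fallback = 0.9) {
  depth <- variants$ref_count + variants$alt_count
  af <- ifelse(depth > 0, variants$alt_count / depth, 0)
  hom_alt <- variants$genotype == "hom_alt" |
    (variants$genotype == "missing" & af >= hom_af_fallback)
  keep <- hom_alt &
    variants$type == "snv" &
    depth >= min_cov & depth <= max_cov
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine the two parents' homozygous SNV sets into a contrasting set
#'
#' A position enters the contrasting set when exactly one parent is
#' homozygous for an alternate allele (the other parent then implicitly
#' carries the reference allele). Positions homozygous-alternate in both
#' parents are excluded: same ALT means the site does not contrast
#' between the pools, different ALT means the site is triallelic.
#'
#' @param p1,p2 Outputs of [filter_parental_variants()] for parent 1
#'   and parent 2.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `p1_allele`, `p2_allele`, `alt_parent` (`"p1"` or `"p2"`), plus
#'   attributes `n_shared` and `n_triallelic` counting exclusions.
#' @export
combine_parental_sets <- function(p1, p2) {
  k1 <- paste(p1$chrom, p1$pos)
  k2 <- paste(p2$chrom, p2$pos)
  shared_keys <- intersect(k1, k2)
  alt1 <- p1$alt[match(shared_keys, k1)]
  alt2 <- p2$alt[match(shared_keys, k2)]
  n_shared <- sum(alt1 == alt2)
  n_triallelic <- sum(alt1 != alt2)

  only1 <- p1[!(k1 %in% shared_keys), , drop = FALSE]
  only2 <- p2[!(k2 %in% shared_keys), , drop = FALSE]
  out <- rbind(
    data.frame(chrom = only1$chrom, pos = only1$pos, ref = only1$ref,
               alt = only1$alt, p1_allele = only1$alt,
               p2_allele = only1$ref, alt_parent = "p1",
               stringsAsFactors = FALSE),
    data.frame(chrom = only2$chrom, pos = only2$pos, ref = only2$ref,
               alt = only2$alt, p1_allele = only2$ref,
               p2_allele = only2$alt, alt_parent = "p2",
               stringsAsFactors = FALSE)
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shared") <- n_shared
  attr(out, "n_triallelic") <- n_triallelic
  out
}

#' Reconstitute F1 allele frequencies from parental read counts
#'
#' Sums the reference and alternate read counts of both parents at each
#' position, emulating the variant set of the F1 hybrid: a true
#' parent-contrasting site receives roughly equal support for both
#' alleles and so shows an alternate-allele frequency near 0.5.
#' Additional count tables (e.g. the pools) may be added via `extra`.
#'
#' @param p1,p2 Unfiltered variant tables from [read_vcf()]; records
#'   homozygous-reference in one parent must be present (with
#'   `alt_count = 0`) for that parent's reference support to count.
#' @param extra Optional list of further variant tables whose counts
#'   are added.
#' @return Data.frame with columns `chrom`, `pos`, `af` (alternate
#'   allele frequency in the summed reads).
#' @export
reconstitute_f1 <- function(p1, p2, extra = NULL) {
  tabs <- c(list(p1, p2), extra)
  all <- do.call(rbind, lapply(tabs, function(x) {
    data.frame(chrom = x$chrom, pos = x$pos,
               ref_count = x$ref_count, alt_count = x$alt_count,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(cbind(ref_count, alt_count) ~ chrom + pos,
                          data = all, FUN = sum)
  depth <- agg$ref_count + agg$alt_count
  out <- data.frame(chrom = agg$chrom, pos = agg$pos,
                    af = ifelse(depth > 0, agg$alt_count / depth, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$af), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict the contrasting set to sites heterozygous in the F1
#'
#' A contrasting site is trustworthy only if the reconstituted F1 looks
#' heterozygous there: its alternate-allele frequency must lie within
#' `[lo, hi]` (bounds inclusive). Sites absent from the frequency map
#' are dropped and counted.
#'
#' @param contrasting Output of [combine_parental_sets()].
#' @param f1_af Output of [reconstitute_f1()].
#' @param lo,hi Inclusive allele-frequency band (defaults 0.2 and 0.8).
#' @return A `gold_standard` object: the retained rows of
#'   `contrasting`, with provenance counters in the `counters`
#'   attribute.
#' @export
filter_f1_heterozygous <- function(contrasting, f1_af, lo = 0.2, hi = 0.8) {
  key_c <- paste(contrasting$chrom, contrasting$pos)
  key_f <- paste(f1_af$chrom, f1_af$pos)
  af <- f1_af$af[match(key_c, key_f)]
  absent <- is.na(af)
  keep <- !absent & af >= lo & af <= hi
  out <- contrasting[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counters") <- c(
    n_contrasting = nrow(contrasting),
    n_absent_from_f1 = sum(absent),
    n_af_outside = sum(!absent & !keep),
    n_final = nrow(out)
  )
  class(out) <- c("gold_standard", class(out))
  out
}

#' Build the gold-standard SNV whitelist from parental variant tables
#'
#' Convenience wrapper chaining [filter_parental_variants()],
#' [combine_parental_sets()], [reconstitute_f1()] and
#' [filter_f1_heterozygous()]. The result is the whitelist of
#' parent-contrasting SNVs used to filter the pool variants.
#'
#' @param p1,p2 Unfiltered variant tables from [read_vcf()].
#' @param min_cov,max_cov Parental depth band (see
#'   [filter_parental_variants()]).
#' @param af_lo,af_hi F1 heterozygosity band (see
#'   [filter_f1_heterozygous()]).
#' @param extra_counts Optional list of further variant tables added to
#'   the F1 reconstitution (e.g. pool tables).
#' @return A `gold_standard` object.
#' @export
build_gold_standard <- function(p1, p2, min_cov = 10, max_cov = 60,
                                af_lo = 0.2, af_hi = 0.8,
                                extra_counts = NULL) {
  f1 <- filter_parental_variants(p1, min_cov, max_cov)
  f2 <- filter_parental_variants(p2, min_cov, max_cov)
  contrasting <- combine_parental_sets(f1, f2)
  f1_af <- reconstitute_f1(p1, p2, extra = extra_counts)
  gold <- filter_f1_heterozygous(contrasting, f1_af, af_lo, af_hi)
  counters <- attr(gold, "counters")
  attr(gold, "counters") <- c(
    n_input_p1 = nrow(p1), n_input_p2 = nrow(p2),
    n_pass_p1 = nrow(f1), n_pass_p2 = nrow(f2),
    counters
  )
  gold
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d contrasting SNVs\n", nrow(x)))
  cnt <- attr(x, "counters")
  if (!is.null(cnt)) {
    cat(paste0("  ", names(cnt), ": ", cnt, collapse = "\n"), "\n")
  }
  invisible(x)
}
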