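#' Two-sided Fisher's exact test on a 2x2 pool allele-count table
#'
#' Tests whether the reference/alternate read split differs between the
#' two pools. Vectorized over sites; each site's table is
#' `rbind(c(ref_h, alt_h), c(ref_l, alt_l))`.
#'
#' @param ref_h,alt_h,ref_l,alt_l Non-negative integer counts
#'   (vectorized, recycled to common length).
#' @return Two-sided p-values; `NA` for all-zero tables (no reads, no
#'   test).
#' @export
fisher_exact_2x2 <- function(ref_h, alt_h, ref_l, alt_l) {
  n <- max(length(ref_h), length(alt_h), length(ref_l), length(alt_l))
  ref_h <- rep_len(as.integer(ref_h), n)
  alt_h <- rep_len(as.integer(alt_h), n)
  ref_l <- rep_len(as.integer(ref_l), n)
  alt_l <- rep_len(as.integer(alt_l), n)
  stopifnot(all(c(ref_h, alt_h, ref_l, alt_l) >= 0L))
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(ref_h[i], ref_l[i], alt_h[i], alt_l[i]), nrow = 2L)
    if (sum(tab) == 0L) return(NA_real_)
    stats::fisher.test(tab)$p.value
  }, numeric(1L))
}

#' Adjust p-values for multiple testing
#'
#' @param p Vector of p-values in (0, 1].
#' @param method `"benjamini-hochberg"` (step-up false discovery rate,
#'   the default) or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("benjamini-hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = switch(method,
                                     "benjamini-hochberg" = "BH",
                                     "bonferroni" = "bonferroni"))
}

#' Call dARCs: sites with significantly differential allele counts
#'
#' Applies [fisher_exact_2x2()] to every record's pool count table,
#' corrects for multiple testing, and flags records with adjusted
#' p-value below `alpha` as statistically meaningful differential
#' allele-specific read counts (dARCs). Records whose table cannot be
#' tested (no reads at all) are dropped.
#'
#' @param records Allele-frequency records from [join_pools()] (any
#'   data.frame with `ref_high`, `alt_high`, `ref_low`, `alt_low`).
#' @param alpha Significance cut-off on the adjusted p-value
#'   (default 0.05).
#' @param method Correction method, see [adjust_pvalues()].
#' @return `records` with columns `p_raw`, `p_adj` and logical
#'   `is_darc` appended.
#' @export
call_darcs <- function(records, alpha = 0.05,
                       method = c("benjamini-hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (nrow(records) == 0L) {
    records$p_raw <- numeric()
    records$p_adj <- numeric()
    records$is_darc <- logical()
    return(records)
  }
  p <- fisher_exact_2x2(records$ref_high, records$alt_high,
                        records$ref_low, records$alt_low)
  drop <- is.na(p)
  if (any(drop)) {
    message(sum(drop), " untestable record(s) (no reads) dropped")
    records <- records[!drop, , drop = FALSE]
    p <- p[!drop]
  }
  records$p_raw <- p
  records$p_adj <- adjust_pvalues(p, method)
  records$is_darc <- records$p_adj < alpha
  rownames(records) <- NULL
  message(sum(records$is_darc), " dARCs among ", nrow(records), " sites")
  records
}
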