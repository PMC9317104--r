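#' Smooth dAF values with a variant-count sliding window
#'
#' Represents each window of `window` consecutive variants (per
#' chromosome, in positional order) by the median dAF of its members;
#' the window advances by `step` variants. The median suppresses
#' isolated noisy sites while keeping genuine frequency shifts visible.
#' Chromosomes with fewer than `window` variants yield an empty track
#' with a warning; a trailing partial window is dropped.
#'
#' @param records Allele-frequency records from [join_pools()], sorted
#'   by position within chromosome.
#' @param window Window size in variants (default 100).
#' @param step Shift in variants (default 5).
#' @return Data.frame with columns `chrom`, `window_start` (position of
#'   the window's first variant), `value` (median dAF) and
#'   `kind = "smoothed_daf"`.
#' @export
smooth_daf <- function(records, window = 100L, step = 5L) {
  out <- lapply(split(records, records$chrom), function(sub) {
    sub <- sub[order(sub$pos), , drop = FALSE]
    n <- nrow(sub)
    if (n < window) {
      warning("chromosome ", sub$chrom[1L], " has ", n,
              " variants (< window of ", window, "); empty track")
      return(NULL)
    }
    offsets <- seq(0L, n - window, by = step)
    data.frame(
      chrom = sub$chrom[1L],
      window_start = sub$pos[offsets + 1L],
      value = vapply(offsets, function(o) {
        stats::median(sub$daf[(o + 1L):(o + window)])
      }, numeric(1L)),
      kind = "smoothed_daf",
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), window_start = numeric(),
                      value = numeric(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized dARC density in bp sliding windows
#'
#' For each window (anchored at position 1, fixed step), the number of
#' dARCs divided by the total number of SNVs in the window. Windows
#' without any SNV emit `NA` rather than 0, so variant deserts remain
#' distinguishable from regions that merely lack significant sites.
#'
#' @param darcs Positions of dARCs on one chromosome.
#' @param all_snvs Positions of all SNVs on the same chromosome.
#' @param chrom Chromosome name for the output.
#' @param chrom_length Chromosome length in bp; windows are laid out up
#'   to this coordinate.
#' @param window Window size in bp (default 100 kbp).
#' @param step Step size in bp (default 30 kbp).
#' @return Data.frame with columns `chrom`, `window_start`, `value`
#'   (fraction in \[0, 1\] or `NA`) and `kind = "darc_density"`.
#' @export
darc_density <- function(darcs, all_snvs, chrom, chrom_length,
                         window = 100000L, step = 30000L) {
  starts <- seq(1L, max(1L, chrom_length - window + 1L), by = step)
  value <- vapply(starts, function(s) {
    e <- s + window - 1L
    n_snv <- sum(all_snvs >= s & all_snvs <= e)
    if (n_snv == 0L) return(NA_real_)
    sum(darcs >= s & darcs <= e) / n_snv
  }, numeric(1L))
  data.frame(chrom = chrom, window_start = starts, value = value,
             kind = "darc_density", stringsAsFactors = FALSE)
}

#' Window mean coverage normalized to the chromosome maximum
#'
#' Computes the mean depth in sliding windows and divides by the
#' largest window mean on the chromosome, so values lie in \[0, 1\]
#' with the best-covered window at exactly 1. An all-zero chromosome
#' yields all zeros.
#'
#' @param track A [coverage_track()] object.
#' @param window Window size in bp (default 100 kbp).
#' @param step Step size in bp (default 30 kbp).
#' @return Data.frame with columns `chrom`, `window_start`, `value` and
#'   `kind = "norm_coverage"`.
#' @export
normalized_mean_coverage <- function(track, window = 100000L,
                                     step = 30000L) {
  len <- length(track$depth)
  starts <- seq(1L, max(1L, len - window + 1L), by = step)
  cum <- c(0, cumsum(as.numeric(track$depth)))
  means <- vapply(starts, function(s) {
    e <- min(s + window - 1L, len)
    (cum[e + 1L] - cum[s]) / (e - s + 1L)
  }, numeric(1L))
  mx <- max(means)
  value <- if (mx > 0) means / mx else means
  data.frame(chrom = track$chrom, window_start = starts, value = value,
             kind = "norm_coverage", stringsAsFactors = FALSE)
}

#' Extract candidate genes for each genomic interval
#'
#' A gene is a candidate for an interval when its body overlaps the
#' interval extended by `flank` bp on both sides by at least one base
#' (so genes merely touching the flank are included).
#'
#' @param intervals Interval data.frame from [detect_intervals()] (or
#'   [read_interval_table()]).
#' @param genes Gene-model data.frame from [read_gff3()].
#' @param flank Border extension in bp (default 5000).
#' @return Data.frame with one row per (interval, gene) pair:
#'   `interval_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `annotation`.
#' @export
extract_candidate_genes <- function(intervals, genes, flank = 5000L) {
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, , drop = FALSE]
    hit <- genes$chrom == iv$chrom &
      genes$end >= iv$start - flank &
      genes$start <= iv$end + flank
    if (!any(hit)) return(NULL)
    cbind(interval_id = iv$interval_id,
          genes[hit, c("gene_id", "chrom", "start", "end", "strand",
                       "annotation")],
          stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(interval_id = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      annotation = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The four effect classes counted as "high impact"; keys are the
# SnpEff ANN effect terms, values the reported class labels.
high_impact_classes <- c(
  stop_gained = "stop_gained",
  stop_lost = "stop_lost",
  frameshift_variant = "frameshift",
  splice_acceptor_variant = "splice_site",
  splice_donor_variant = "splice_site"
)

#' Read effect-annotated variants from a SnpEff-style VCF
#'
#' Extracts the `ANN` INFO field of each record together with its
#' coordinates and alleles, for use with [filter_high_impact()].
#'
#' @param path Path to an effect-annotated VCF.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`, `ann`
#'   (the raw ANN string, `NA` when absent).
#' @export
read_ann_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ann <- vcfR::extract.info(vcf, element = "ANN")
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT, ann = ann,
             stringsAsFactors = FALSE)
}

#' Filter effect-annotated variants for high-impact classes
#'
#' Keeps variants whose annotation (SnpEff `ANN` dialect:
#' `allele|effect|impact|gene_name|gene_id|...`, comma-separated
#' entries, `&`-joined effect terms) contains one of the four
#' high-impact classes: stop gained, stop lost, frameshift, or splice
#' site (donor/acceptor). Optionally restricts to candidate genes and
#' attaches pool allele frequencies.
#'
#' @param records Data.frame from [read_ann_vcf()].
#' @param candidate_genes Optional vector of gene IDs (e.g. from
#'   [extract_candidate_genes()]); variants in other genes are dropped.
#' @param afs Optional allele-frequency records from [join_pools()];
#'   matched by `(chrom, pos)` to attach `af_high` / `af_low`.
#' @return Data.frame with columns `chrom`, `pos`, `gene_id`,
#'   `effect_class`, `af_high`, `af_low`.
#' @export
filter_high_impact <- function(records, candidate_genes = NULL,
                               afs = NULL) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), effect_class = character(),
                      af_high = numeric(), af_low = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  n_bad <- 0L
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ann <- records$ann[i]
    if (is.na(ann) || !nzchar(ann)) return(NULL)
    entries <- strsplit(ann, ",", fixed = TRUE)[[1L]]
    hits <- lapply(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1L]]
      if (length(f) < 4L) {
        n_bad <<- n_bad + 1L
        return(NULL)
      }
      effects <- strsplit(f[2L], "&", fixed = TRUE)[[1L]]
      cls <- unique(stats::na.omit(high_impact_classes[effects]))
      if (length(cls) == 0L) return(NULL)
      gene <- if (length(f) >= 5L && nzchar(f[5L])) f[5L] else f[4L]
      data.frame(chrom = records$chrom[i], pos = records$pos[i],
                 gene_id = gene, effect_class = cls,
                 stringsAsFactors = FALSE)
    })
    hits <- hits[!vapply(hits, is.null, logical(1L))]
    if (length(hits) == 0L) NULL else do.call(rbind, hits)
  })
  if (n_bad > 0L) warning(n_bad, " unparsable ANN entr(ies) skipped")
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(candidate_genes)) {
    out <- out[out$gene_id %in% candidate_genes, , drop = FALSE]
  }
  if (!is.null(afs)) {
    idx <- match(paste(out$chrom, out$pos), paste(afs$chrom, afs$pos))
    out$af_high <- afs$af_high[idx]
    out$af_low <- afs$af_low[idx]
  } else {
    out$af_high <- NA_real_
    out$af_low <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Tally genomic intervals per chromosome
#'
#' @param intervals Interval data.frame with a `chrom` column.
#' @return Data.frame with columns `chrom` and `n_intervals`, one row
#'   per chromosome present, plus the grand total in the `total`
#'   attribute.
#' @export
chromosome_summary <- function(intervals) {
  if (nrow(intervals) == 0L) {
    out <- data.frame(chrom = character(), n_intervals = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- table(intervals$chrom)
  out <- data.frame(chrom = names(tab),
                    n_intervals = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(intervals)
  out
}
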