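#' Cluster sorted dARC positions by a maximum-gap rule
#'
#' Chains positions into maximal runs in which every adjacent pair is
#' strictly less than `max_gap` apart. A gap of exactly `max_gap`
#' splits. The gap rule prevents sparse runs of isolated dARCs from
#' bridging unrelated dense regions into one oversized interval.
#'
#' @param positions Sorted ascending positions on one chromosome.
#' @param max_gap Splitting distance in bp (default 50000).
#' @return List of numeric vectors, one per cluster, in genomic order.
#' @export
cluster_darcs <- function(positions, max_gap = 50000L) {
  if (length(positions) == 0L) return(list())
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  breaks <- which(diff(positions) >= max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(positions))
  mapply(function(s, e) positions[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Validate a dARC cluster by count and spread rules
#'
#' A cluster seeds an interval only if (a) it contains at least
#' `min_darcs` dARCs and (b) at least `spread_count` of them are
#' pairwise more than `spread_dist` apart. The spread rule discards
#' pile-ups of variants from a single DNA fragment, which can be an
#' artifact. The pairwise-spread subset is found greedily left to
#' right, keeping each dARC that is more than `spread_dist` from the
#' last kept one.
#'
#' @param positions Sorted positions of one cluster.
#' @param min_darcs Minimum number of member dARCs (default 4).
#' @param spread_count Required size of the well-spread subset
#'   (default 3).
#' @param spread_dist Minimum pairwise distance of that subset in bp
#'   (default 1000).
#' @return `TRUE` iff the cluster passes both rules.
#' @export
validate_cluster <- function(positions, min_darcs = 4L, spread_count = 3L,
                             spread_dist = 1000L) {
  if (length(positions) < min_darcs) return(FALSE)
  kept <- 1L
  last <- positions[1L]
  for (p in positions[-1L]) {
    if (p - last > spread_dist) {
      kept <- kept + 1L
      last <- p
      if (kept >= spread_count) return(TRUE)
    }
  }
  kept >= spread_count
}

#' Merge clusters separated by zero-coverage regions
#'
#' Shared deletions produce zero-coverage regions (ZCRs) in which no
#' variants — hence no dARCs — can exist, artificially splitting one
#' trait locus into several clusters. Two adjacent clusters are merged
#' when at least `zcr_gap_fraction` of the gap between them is covered
#' by ZCRs, regardless of the gap's length; merging is iterated to a
#' fixed point.
#'
#' @param clusters List of sorted position vectors from
#'   [cluster_darcs()], in genomic order.
#' @param zcrs ZCR data.frame from [detect_zcrs()] (same chromosome).
#' @param zcr_gap_fraction Minimum fraction of the inter-cluster gap
#'   covered by ZCRs (default 0.5).
#' @return List of clusters after merging.
#' @export
merge_across_zcrs <- function(clusters, zcrs, zcr_gap_fraction = 0.5) {
  if (length(clusters) < 2L || is.null(zcrs) || nrow(zcrs) == 0L) {
    return(clusters)
  }
  covered_bp <- function(gap_start, gap_end) {
    # bp of [gap_start, gap_end] intersected with any ZCR
    s <- pmax(zcrs$start, gap_start)
    e <- pmin(zcrs$end, gap_end)
    sum(pmax(0L, e - s + 1L))
  }
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(clusters)) {
      gap_start <- max(clusters[[i]]) + 1L
      gap_end <- min(clusters[[i + 1L]]) - 1L
      gap_len <- gap_end - gap_start + 1L
      frac <- if (gap_len <= 0L) 1 else covered_bp(gap_start, gap_end) / gap_len
      if (frac >= zcr_gap_fraction) {
        clusters[[i]] <- c(clusters[[i]], clusters[[i + 1L]])
        clusters[[i + 1L]] <- NULL
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  clusters
}

#' Threshold, rank and label genomic intervals
#'
#' Keeps intervals with at least `min_darc_cutoff` member dARCs, ranks
#' them by descending dARC count (ties broken by larger size, then
#' smaller start) and assigns IDs of the form
#' `<chromosome-short>_<trait>_<k>`, numbering intervals within each
#' chromosome by ascending start position.
#'
#' @param intervals Data.frame with columns `chrom`, `start`, `end`,
#'   `n_darcs` (one row per validated cluster).
#' @param min_darc_cutoff Minimum dARC count for reporting (the
#'   original analyses used 100 for the glucosinolate trait and 65 for
#'   seed protein content).
#' @param trait_label Short trait tag used in interval IDs (e.g.
#'   `"GSL"`).
#' @return Data.frame with columns `interval_id`, `chrom`, `start`,
#'   `end`, `size` (`end - start`), `n_darcs`, `rank`, ordered by
#'   chromosome and start.
#' @export
rank_and_threshold <- function(intervals, min_darc_cutoff = 4L,
                               trait_label = "TRAIT") {
  keep <- intervals[intervals$n_darcs >= min_darc_cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(interval_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), size = numeric(),
                      n_darcs = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  keep$size <- keep$end - keep$start
  ord <- order(-keep$n_darcs, -keep$size, keep$start)
  keep$rank[ord] <- seq_len(nrow(keep))
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  chrom_short <- sub("^chr", "", keep$chrom)
  k <- stats::ave(keep$start, keep$chrom, FUN = seq_along)
  keep$interval_id <- sprintf("%s_%s_%d", chrom_short, trait_label, k)
  rownames(keep) <- NULL
  keep[, c("interval_id", "chrom", "start", "end", "size",
           "n_darcs", "rank")]
}

#' Detect trait-associated genomic intervals from dARC calls
#'
#' Full interval detection: per chromosome, the positions flagged
#' `is_darc` are clustered by the maximum-gap rule, clusters split by
#' zero-coverage regions are re-merged, clusters failing the
#' count/spread rules are discarded, and the survivors are thresholded,
#' ranked and labelled. Interval boundaries are the first and last
#' member dARC; the reported size is `end - start`.
#'
#' @param darcs dARC table from [call_darcs()].
#' @param zcrs Optional ZCR table from [detect_zcrs()] (may cover
#'   several chromosomes).
#' @param max_gap,min_darcs,spread_count,spread_dist,zcr_gap_fraction
#'   Rule parameters, see [cluster_darcs()], [validate_cluster()] and
#'   [merge_across_zcrs()].
#' @param min_darc_cutoff,trait_label Reporting parameters, see
#'   [rank_and_threshold()].
#' @return Ranked interval data.frame (see [rank_and_threshold()]).
#' @export
detect_intervals <- function(darcs, zcrs = NULL, max_gap = 50000L,
                             min_darcs = 4L, spread_count = 3L,
                             spread_dist = 1000L, zcr_gap_fraction = 0.5,
                             min_darc_cutoff = 4L, trait_label = "TRAIT") {
  darcs <- darcs[darcs$is_darc, , drop = FALSE]
  per_chrom <- split(darcs$pos, darcs$chrom)
  rows <- lapply(names(per_chrom), function(chr) {
    pos <- sort(per_chrom[[chr]])
    clusters <- cluster_darcs(pos, max_gap)
    if (!is.null(zcrs)) {
      zc <- zcrs[zcrs$chrom == chr, , drop = FALSE]
      clusters <- merge_across_zcrs(clusters, zc, zcr_gap_fraction)
    }
    clusters <- Filter(function(cl) {
      validate_cluster(cl, min_darcs, spread_count, spread_dist)
    }, clusters)
    if (length(clusters) == 0L) return(NULL)
    data.frame(
      chrom = chr,
      start = vapply(clusters, min, numeric(1L)),
      end = vapply(clusters, max, numeric(1L)),
      n_darcs = vapply(clusters, length, integer(1L)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(rank_and_threshold(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 n_darcs = integer(), stringsAsFactors = FALSE),
      min_darc_cutoff, trait_label))
  }
  rank_and_threshold(do.call(rbind, rows), min_darc_cutoff, trait_label)
}
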