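#' Detect zero-coverage regions shared by both pools
#'
#' Scans a chromosome in non-overlapping fixed windows (tiled from
#' position 1; a trailing partial window is ignored). A window
#' qualifies when every base inside it has depth 0 in *both* pools —
#' such regions carry no variants, so they are typically shared
#' deletions that would otherwise split dARC intervals. Adjacent
#' qualifying windows are merged into one region.
#'
#' @param cov_high,cov_low [coverage_track()] objects for the same
#'   chromosome, same length.
#' @param window Window size in bp (default 200).
#' @return Data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive, multiples of the window size) and `n_windows`.
#' @export
detect_zcrs <- function(cov_high, cov_low, window = 200L) {
  if (length(cov_high$depth) != length(cov_low$depth)) {
    stop("coverage track length mismatch: ",
         length(cov_high$depth), " vs ", length(cov_low$depth))
  }
  if (cov_high$chrom != cov_low$chrom) {
    stop("coverage tracks are from different chromosomes")
  }
  n_win <- length(cov_high$depth) %/% window
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (n_win == 0L) return(empty)
  used <- n_win * window
  total <- cov_high$depth[seq_len(used)] + cov_low$depth[seq_len(used)]
  win_sum <- colSums(matrix(total, nrow = window))
  qualifies <- win_sum == 0L
  if (!any(qualifies)) return(empty)
  runs <- rle(qualifies)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1L
  sel <- runs$values
  data.frame(
    chrom = cov_high$chrom,
    start = (starts_idx[sel] - 1L) * window + 1L,
    end = ends_idx[sel] * window,
    n_windows = runs$lengths[sel],
    stringsAsFactors = FALSE
  )
}

#' Mean read depth of a track over a gene body
#'
#' @param track A [coverage_track()] object.
#' @param gene One row of a gene-model data.frame (`chrom`, `start`,
#'   `end`).
#' @return Arithmetic mean depth over `[start, end]`.
#' @export
gene_mean_coverage <- function(track, gene) {
  if (gene$chrom != track$chrom) {
    stop("gene ", gene$gene_id, " is on ", gene$chrom,
         ", track is ", track$chrom)
  }
  if (gene$end > length(track$depth) || gene$start < 1L) {
    stop("gene ", gene$gene_id, " lies outside the coverage track")
  }
  mean(track$depth[gene$start:gene$end])
}

#' Detect gene-level presence-absence variations between pools
#'
#' For every gene, computes the mean depth in each pool and normalizes
#' it by that pool's genome-wide mean depth, making the two pools
#' comparable regardless of sequencing effort. A gene is called a PAV
#' when the raw mean depth in at least one pool falls below `mincov`
#' (no/extremely low coverage) while the normalized depths differ by at
#' least `ratio_min`-fold. In an F2 cross, a gene deleted in one parent
#' under opposite pool selection is expected near a 3-fold normalized
#' contrast (one pool retaining about 1/3 of the background coverage).
#'
#' Genes covered in neither pool (e.g. inside a shared deletion) show
#' no contrast and are not called.
#'
#' @param genes Gene-model data.frame (see [read_gff3()]).
#' @param cov_high,cov_low Named lists of [coverage_track()] objects
#'   keyed by chromosome (one pool each).
#' @param mincov Raw mean-depth ceiling for the depleted pool
#'   (default 10).
#' @param ratio_min Minimum normalized coverage ratio (default 2).
#' @return Data.frame ranked by descending `ratio` with columns
#'   `gene_id`, `chrom`, `start`, `end`, `raw_cov_high`, `raw_cov_low`,
#'   `norm_cov_high`, `norm_cov_low`, `ratio` (larger normalized depth
#'   over smaller; `Inf` when the smaller is 0) and `direction` (which
#'   pool is depleted).
#' @export
detect_pavs <- function(genes, cov_high, cov_low, mincov = 10,
                        ratio_min = 2) {
  pool_mean <- function(tracks) {
    mean(unlist(lapply(tracks, function(t) mean(t$depth))))
  }
  mean_high <- pool_mean(cov_high)
  mean_low <- pool_mean(cov_low)
  genes <- genes[genes$chrom %in% names(cov_high) &
                   genes$chrom %in% names(cov_low), , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    raw_h <- gene_mean_coverage(cov_high[[g$chrom]], g)
    raw_l <- gene_mean_coverage(cov_low[[g$chrom]], g)
    if (min(raw_h, raw_l) >= mincov) return(NULL)
    norm_h <- if (mean_high > 0) raw_h / mean_high else 0
    norm_l <- if (mean_low > 0) raw_l / mean_low else 0
    if (norm_h == 0 && norm_l == 0) return(NULL)
    ratio <- max(norm_h, norm_l) / min(norm_h, norm_l)
    if (ratio < ratio_min) return(NULL)
    data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
      raw_cov_high = raw_h, raw_cov_low = raw_l,
      norm_cov_high = norm_h, norm_cov_low = norm_l,
      ratio = ratio,
      direction = if (norm_h < norm_l) "high" else "low",
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), raw_cov_high = numeric(), raw_cov_low = numeric(),
      norm_cov_high = numeric(), norm_cov_low = numeric(),
      ratio = numeric(), direction = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ratio, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
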