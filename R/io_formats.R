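#' Read per-sample biallelic variants from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per record for the named
#' sample, carrying the allele-specific read counts (the `AD` FORMAT
#' field) that all downstream pool statistics are based on.
#'
#' Multiallelic records (more than one ALT allele) are rejected, not
#' split: such sites cannot contrast cleanly between two homozygous
#' parents and are excluded from every downstream step. The number
#' rejected is reported in the `n_multiallelic` attribute. Records
#' without an `AD` value for the sample are skipped and counted in
#' `n_no_ad`. InDels are retained with `type = "indel"` so that
#' SNV-only consumers can drop them.
#'
#' @param path Path to a VCF file (plain text or bgzip).
#' @param sample Sample name as it appears in the VCF header.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `filter_status`, `genotype`
#'   (`"hom_ref"`, `"het"`, `"hom_alt"` or `"missing"`) and `type`
#'   (`"snv"` or `"indel"`), plus attributes `n_multiallelic` and
#'   `n_no_ad`.
#' @export
read_vcf <- function(path, sample) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path)
  }
  n_body <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (n_body == 0L) {
    return(empty_variant_frame(n_multiallelic = 0L, n_no_ad = 0L))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(empty_variant_frame(n_multiallelic = 0L, n_no_ad = 0L))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    stop("Sample '", sample, "' not present in VCF header (found: ",
         paste(samples, collapse = ", "), ")")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample]
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."
  n_multi <- sum(multi)
  no_ad <- !multi & (is.na(ad) | ad == "." | !grepl(",", ad, fixed = TRUE))
  n_no_ad <- sum(no_ad)
  if (n_no_ad > 0L) {
    message(n_no_ad, " record(s) without AD skipped")
  }
  keep <- !multi & !no_ad

  ad_split <- strsplit(ad[keep], ",", fixed = TRUE)
  ref_count <- suppressWarnings(as.integer(vapply(ad_split, `[`, "", 1L)))
  alt_count <- suppressWarnings(as.integer(vapply(ad_split, `[`, "", 2L)))
  bad <- is.na(ref_count) | is.na(alt_count)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed AD skipped")
  }

  out <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    ref_count = ref_count,
    alt_count = alt_count,
    filter_status = ifelse(is.na(fix$FILTER[keep]), ".", fix$FILTER[keep]),
    genotype = classify_genotype(gt[keep]),
    stringsAsFactors = FALSE
  )
  out$type <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                     "snv", "indel")
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- n_multi
  attr(out, "n_no_ad") <- n_no_ad
  out
}

empty_variant_frame <- function(n_multiallelic = 0L, n_no_ad = 0L) {
  out <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), ref_count = integer(), alt_count = integer(),
    filter_status = character(), genotype = character(),
    type = character(), stringsAsFactors = FALSE
  )
  attr(out, "n_multiallelic") <- n_multiallelic
  attr(out, "n_no_ad") <- n_no_ad
  out
}

classify_genotype <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out
}

#' Write a variant table as a minimal single-sample VCF
#'
#' Emits the subset of VCF 4.2 the pipeline itself consumes: one sample
#' with `GT:AD:DP`. Used by the simulator so that simulated experiments
#' round-trip through [read_vcf()].
#'
#' @param variants Data.frame as returned by [read_vcf()].
#' @param path Output file path.
#' @param sample Sample name for the header column.
#' @param contigs Optional named vector of contig lengths for `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = "sample", contigs = NULL) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mbsmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(contigs)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), as.integer(contigs)))
  }
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample, sep = "\t"))
  if (nrow(variants) > 0L) {
    body <- paste(
      variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
      variants$filter_status, ".", "GT:AD:DP",
      paste0(gt_code[variants$genotype], ":",
             variants$ref_count, ",", variants$alt_count, ":",
             variants$ref_count + variants$alt_count),
      sep = "\t"
    )
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a per-base coverage track
#'
#' @param chrom Chromosome name.
#' @param depth Integer vector; element `i` is the read depth at 1-based
#'   position `i`.
#' @param pool_id Label of the pool the track belongs to.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, depth, pool_id = NA_character_) {
  stopifnot(all(depth >= 0))
  structure(
    list(chrom = chrom, depth = as.integer(depth), pool_id = pool_id),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s (%s): %d bp, mean depth %.2f\n",
              x$chrom, x$pool_id, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Read per-base coverage from a 3-column TSV
#'
#' The file dialect is `chromosome<TAB>position<TAB>depth` with 1-based
#' positions. The file may be sparse: positions absent from the file get
#' depth 0. Within a chromosome positions must be strictly increasing.
#'
#' @param path Path to the coverage TSV.
#' @param chrom_lengths Optional named integer vector of chromosome
#'   lengths; tracks are padded with zeros to that length. Without it a
#'   chromosome's length is the largest position seen.
#' @param pool_id Label attached to every track.
#' @return Named list of [coverage_track()] objects, one per chromosome.
#' @export
read_coverage <- function(path, chrom_lengths = NULL, pool_id = NA_character_) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "depth"),
                           colClasses = c("character", "integer", "integer"))
  chroms <- unique(c(tab$chrom, names(chrom_lengths)))
  out <- list()
  for (chr in chroms) {
    sub <- tab[tab$chrom == chr, , drop = FALSE]
    if (nrow(sub) > 1L && any(diff(sub$pos) <= 0L)) {
      stop("non-monotone positions in coverage file for ", chr)
    }
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      chrom_lengths[[chr]]
    } else if (nrow(sub) > 0L) {
      max(sub$pos)
    } else 0L
    depth <- integer(len)
    if (nrow(sub) > 0L) depth[sub$pos] <- sub$depth
    out[[chr]] <- coverage_track(chr, depth, pool_id)
  }
  out
}

#' Write coverage tracks as a sparse 3-column TSV
#'
#' Inverse of [read_coverage()]: only nonzero positions are written, so
#' re-reading with the original chromosome lengths reproduces the dense
#' track exactly.
#'
#' @param tracks Named list of [coverage_track()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in tracks) {
    nz <- which(tr$depth > 0L)
    if (length(nz) > 0L) {
      utils::write.table(
        data.frame(tr$chrom, nz, tr$depth[nz]),
        con, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
      )
    }
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only features of the requested type (default `gene`) are returned,
#' with the 1-based inclusive coordinates of the GFF3 convention.
#' Features with `end < start` are skipped with a warning rather than
#' aborting the whole file.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to extract.
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `annotation` (free text, possibly empty).
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  if (any(!ok)) warning(sum(!ok), " malformed GFF3 line(s) skipped")
  fields <- fields[ok]
  mat <- do.call(rbind, fields)
  sel <- mat[, 3L] == feature_type
  mat <- mat[sel, , drop = FALSE]
  start <- as.integer(mat[, 4L])
  end <- as.integer(mat[, 5L])
  bad <- end < start
  if (any(bad)) {
    warning(sum(bad), " ", feature_type,
            " feature(s) with end < start skipped")
    mat <- mat[!bad, , drop = FALSE]
    start <- start[!bad]
    end <- end[!bad]
  }
  attrs <- mat[, 9L]
  gene_id <- sub(".*ID=([^;]+).*", "\\1", attrs)
  gene_id[!grepl("ID=", attrs)] <- NA_character_
  note <- sub(".*Note=([^;]+).*", "\\1", attrs)
  note[!grepl("Note=", attrs)] <- ""
  data.frame(
    gene_id = gene_id, chrom = mat[, 1L],
    start = start, end = end, strand = mat[, 7L],
    annotation = note, stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#'
#' @param genes Data.frame as returned by [read_gff3()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  header <- "##gff-version 3"
  body <- if (nrow(genes) > 0L) {
    attrs <- paste0("ID=", genes$gene_id,
                    ifelse(nzchar(genes$annotation),
                           paste0(";Note=", genes$annotation), ""))
    paste(genes$chrom, "mbsmap", "gene", genes$start, genes$end, ".",
          genes$strand, ".", attrs, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genomic-interval report as TSV
#'
#' Column layout follows the published interval tables: interval ID,
#' chromosome, size in bp (defined as `end - start`), start and end.
#'
#' @param intervals Data.frame with columns `interval_id`, `chrom`,
#'   `start`, `end` (and optionally `n_darcs`, `rank`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(intervals, path) {
  out <- data.frame(
    Interval_ID = intervals$interval_id,
    Chromosome = intervals$chrom,
    Size_bp = intervals$end - intervals$start,
    Start_bp = intervals$start,
    End_bp = intervals$end,
    stringsAsFactors = FALSE
  )
  if (!is.null(intervals$n_darcs)) out$n_dARCs <- intervals$n_darcs
  if (!is.null(intervals$rank)) out$Rank <- intervals$rank
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genomic-interval report written by [write_interval_table()]
#'
#' Also reads published interval tables stored in the same five-column
#' layout. Thousands separators (commas) in numeric columns are
#' tolerated.
#'
#' @param path Path to the interval TSV.
#' @return Data.frame with columns `interval_id`, `chrom`, `size`,
#'   `start`, `end`.
#' @export
read_interval_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  strip <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
  data.frame(
    interval_id = tab[[1L]],
    chrom = tab[[2L]],
    size = strip(tab[[3L]]),
    start = strip(tab[[4L]]),
    end = strip(tab[[5L]]),
    stringsAsFactors = FALSE
  )
}

#' Export intervals or regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start - 1` / `end` are written.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end` and
#'   optionally a name column (`interval_id` or `gene_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions$interval_id
  if (is.null(name)) name <- regions$gene_id
  if (is.null(name)) name <- rep(".", nrow(regions))
  out <- data.frame(regions$chrom, regions$start - 1L, regions$end, name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
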