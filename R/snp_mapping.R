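# Map candidate SNP loci into called enhancer regions.

#' Load single-base SNP loci from a BED file
#'
#' Accepts BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`) with
#' an optional seventh `population` column. Every interval must span
#' exactly one base; multi-base rows are rejected with their row number.
#'
#' @param path Path to the BED file (no header).
#' @return A data.frame with columns `snp_id`, `chrom`, `pos0`, `strand`,
#'   `population` (empty string when absent from the file).
#' @export
load_snp_bed <- function(path) {
  if (!file.exists(path)) {
    stop("SNP BED file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 6) {
    stop("SNP BED must have at least 6 columns: ", path, call. = FALSE)
  }
  names(df)[1:6] <- c("chrom", "start0", "end0", "name", "score", "strand")
  pop <- if (ncol(df) >= 7) df[[7]] else ""
  start0 <- as.integer(df$start0)
  end0 <- as.integer(df$end0)
  wide <- which(end0 - start0 != 1L)
  if (length(wide) > 0) {
    stop(sprintf("SNP loci must be single-base intervals; row(s) %s of %s span more",
                 paste(wide, collapse = ", "), path), call. = FALSE)
  }
  out <- data.frame(snp_id = df$name,
                    chrom = normalize_chrom(df$chrom),
                    pos0 = start0,
                    strand = df$strand,
                    population = pop)
  if (anyDuplicated(out$snp_id)) {
    stop("duplicate snp_id in ", path, call. = FALSE)
  }
  out
}

#' Write SNP loci as BED6+1
#'
#' Columns: chrom, start, end, snp_id, score 0, strand, population.
#' Accepts either the fixture layout (`start0`/`end0`) or the loader
#' layout (`pos0`).
#'
#' @param snps SNP-locus data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_snp_bed <- function(snps, path) {
  pos0 <- if ("pos0" %in% names(snps)) snps$pos0 else snps$start0
  out <- data.frame(chrom = snps$chrom,
                    start0 = pos0,
                    end0 = pos0 + 1L,
                    name = snps$snp_id,
                    score = 0L,
                    strand = snps$strand,
                    population = snps$population)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intersect SNP loci with enhancer regions
#'
#' Returns exactly the SNPs whose position lies inside a region, using
#' half-open containment (`start0 <= pos0 < end0`), each paired with its
#' unique containing region. Regions must be sorted and non-overlapping
#' within each chromosome. SNPs on chromosomes absent from the region set
#' simply do not match; chromosomes absent from the coverage data should
#' be filtered (and logged) upstream.
#'
#' @param snps SNP-locus data.frame (see [load_snp_bed()]).
#' @param regions Region data.frame from [call_enhancers()].
#' @param ratio Optional `ratio_track` list (named by chromosome) used to
#'   report the log2 ratio at each hit; `NA` otherwise.
#' @return A data.frame sorted by (`chrom`, `pos0`) with columns `snp_id`,
#'   `chrom`, `pos0`, `strand`, `population`, `region_start0`,
#'   `region_end0`, `ratio_at_snp`.
#' @export
intersect_snps <- function(snps, regions, ratio = NULL) {
  if (nrow(regions) > 0) {
    ord <- order(regions$chrom, regions$start0)
    if (!identical(ord, seq_len(nrow(regions)))) {
      stop("regions must be sorted by (chrom, start0)", call. = FALSE)
    }
    by_chr <- split(regions, regions$chrom)
    for (sub in by_chr) {
      if (nrow(sub) > 1 &&
          any(sub$start0[-1] < sub$end0[-nrow(sub)])) {
        stop("regions must be non-overlapping within a chromosome",
             call. = FALSE)
      }
    }
  }
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos0 = integer(0), strand = character(0),
                      population = character(0),
                      region_start0 = integer(0),
                      region_end0 = integer(0),
                      ratio_at_snp = numeric(0))
  if (nrow(snps) == 0 || nrow(regions) == 0) return(empty)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos0 + 1L, width = 1L))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start0 + 1L,
                                                    end = regions$end0))
  hits <- GenomicRanges::findOverlaps(snp_gr, reg_gr)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(snp_id = snps$snp_id[qi],
                    chrom = snps$chrom[qi],
                    pos0 = snps$pos0[qi],
                    strand = snps$strand[qi],
                    population = snps$population[qi],
                    region_start0 = regions$start0[si],
                    region_end0 = regions$end0[si],
                    ratio_at_snp = NA_real_)
  if (!is.null(ratio)) {
    for (i in seq_len(nrow(out))) {
      rt <- ratio[[out$chrom[i]]]
      if (!is.null(rt)) {
        bin <- out$pos0[i] %/% rt$bin_width + 1L
        out$ratio_at_snp[i] <- as.numeric(rt$values[bin])
      }
    }
  }
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write mapped enhancer SNPs to TSV
#' @param enhancer_snps Data.frame from [intersect_snps()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_enhancer_snps <- function(enhancer_snps, path) {
  write_tsv(enhancer_snps, path)
}
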