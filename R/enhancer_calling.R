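# Enhancer calling from paired histone-mark coverage.
#
# Enhancers carry strong H3K4me1 and comparatively weak H3K4me3; promoters
# show the reverse. The caller therefore computes per-bin read coverage for
# the two marks, forms log2((me1 + pc) / (me3 + pc)) after optional
# reads-per-million scaling, and reports maximal runs of bins where the
# ratio exceeds a threshold. Coverage vectors are held as run-length
# encodings so whole chromosomes stay cheap at single-base resolution.

#' Load read alignments from the simplified read TSV dialect
#'
#' The dialect is a headered TSV with columns `chrom`, `start0`, `end0`
#' (0-based half-open), one aligned read per row.
#'
#' @param path Path to the read TSV.
#' @return A data.frame with columns `chrom`, `start0`, `end0`.
#' @export
load_reads_tsv <- function(path) {
  df <- read_strict_tsv(path, c("chrom", "start0", "end0"), "read")
  df <- df[, c("chrom", "start0", "end0")]
  df$start0 <- as.integer(parse_numeric_column(df$start0, "start0", path))
  df$end0 <- as.integer(parse_numeric_column(df$end0, "end0", path))
  if (any(df$end0 <= df$start0)) {
    stop("read with end0 <= start0 in ", path, call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Load read alignments from a BAM file
#'
#' Only mapped reads are used; each becomes the interval
#' `[pos - 1, pos - 1 + qwidth)` in 0-based half-open coordinates.
#'
#' @param path Path to an indexed or unindexed BAM file.
#' @return A data.frame with columns `chrom`, `start0`, `end0`.
#' @export
load_reads_bam <- function(path) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  df <- data.frame(chrom = as.character(res$rname),
                   start0 = res$pos - 1L,
                   end0 = res$pos - 1L + res$qwidth)
  df[order(df$chrom, df$start0), , drop = FALSE]
}

#' Load read alignments, dispatching on file extension
#'
#' `.bam` files go through [load_reads_bam()], anything else through
#' [load_reads_tsv()]; both read paths yield identical coverage.
#'
#' @param path Path to a BAM or read-TSV file.
#' @return A data.frame with columns `chrom`, `start0`, `end0`.
#' @export
load_reads <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) load_reads_bam(path)
  else load_reads_tsv(path)
}

new_coverage_track <- function(chrom, chrom_length, bin_width, depths,
                               library_size) {
  structure(list(chrom = chrom,
                 chrom_length = as.integer(chrom_length),
                 bin_width = as.integer(bin_width),
                 depths = depths,
                 library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s (%d bp, bin %d bp, %d bins, library %d reads)\n",
              x$chrom, x$chrom_length, x$bin_width, length(x$depths),
              x$library_size))
  invisible(x)
}

#' Compute per-bin read coverage for one track
#'
#' At `bin_width = 1` a bin's depth is the number of reads covering that
#' base; at larger widths it is the number of reads overlapping any base
#' of the bin. Reads extending past the chromosome end are clipped with a
#' warning; reads on a chromosome absent from `chrom_lengths` are an
#' error. `library_size` (total reads used, summed over chromosomes) is
#' recorded on every track for later normalization.
#'
#' @param reads Read data.frame (`chrom`, `start0`, `end0`) as produced by
#'   [load_reads()] or [simulate_reads()].
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param bin_width Bin width in bp (default 1, per-base coverage).
#' @return A named list of `coverage_track` objects, one per chromosome in
#'   `chrom_lengths` (empty chromosomes get all-zero tracks).
#' @export
compute_coverage <- function(reads, chrom_lengths, bin_width = 1) {
  stopifnot(bin_width >= 1, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  bin_width <- as.integer(bin_width)
  unknown <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("reads on unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  clipped <- reads
  for (chr in names(chrom_lengths)) {
    sel <- clipped$chrom == chr
    over <- sel & clipped$end0 > chrom_lengths[[chr]]
    if (any(over)) {
      warning(sprintf("%d read(s) extend past the end of %s; clipped",
                      sum(over), chr), call. = FALSE)
      clipped$end0[over] <- chrom_lengths[[chr]]
    }
  }
  clipped <- clipped[clipped$end0 > clipped$start0, , drop = FALSE]
  lib <- nrow(clipped)
  out <- vector("list", length(chrom_lengths))
  names(out) <- names(chrom_lengths)
  for (chr in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[chr]])
    sub <- clipped[clipped$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start0 + 1L, end = sub$end0)
    if (bin_width == 1L) {
      depths <- IRanges::coverage(ir, width = L)
    } else {
      n_bins <- ceiling(L / bin_width)
      starts <- seq.int(1L, by = bin_width, length.out = n_bins)
      bins <- IRanges::IRanges(start = starts,
                               end = pmin(starts + bin_width - 1L, L))
      depths <- S4Vectors::Rle(IRanges::countOverlaps(bins, ir))
    }
    out[[chr]] <- new_coverage_track(chr, L, bin_width, depths, lib)
  }
  out
}

new_ratio_track <- function(chrom, chrom_length, bin_width, values,
                            pseudocount) {
  structure(list(chrom = chrom,
                 chrom_length = as.integer(chrom_length),
                 bin_width = as.integer(bin_width),
                 values = values,
                 pseudocount = pseudocount),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %s (%d bp, bin %d bp, pseudocount %g)\n",
              x$chrom, x$chrom_length, x$bin_width, x$pseudocount))
  invisible(x)
}

#' Per-bin log2 mark ratio between two coverage tracks
#'
#' Computes `log2((me1' + pseudocount) / (me3' + pseudocount))` per bin,
#' where the primed depths are the raw depths optionally scaled to
#' reads-per-million via each track's library size. The pseudocount keeps
#' the ratio finite where either mark has zero coverage.
#'
#' @param me1 `coverage_track` for the H3K4me1 (enhancer) mark.
#' @param me3 `coverage_track` for the H3K4me3 (promoter) mark, same
#'   chromosome and bin width.
#' @param pseudocount Positive depth offset added to both scaled tracks
#'   (default 1, the standard Laplace choice).
#' @param normalize Scale each track to reads-per-million before the ratio
#'   (default `TRUE`; the two marks are independently sequenced libraries).
#' @return A `ratio_track` object.
#' @export
ratio_track <- function(me1, me3, pseudocount = 1, normalize = TRUE) {
  stopifnot(inherits(me1, "coverage_track"), inherits(me3, "coverage_track"))
  if (me1$chrom != me3$chrom || me1$bin_width != me3$bin_width ||
      length(me1$depths) != length(me3$depths)) {
    stop("tracks must share chromosome, bin width and length",
         call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  d1 <- me1$depths
  d3 <- me3$depths
  if (normalize) {
    if (me1$library_size <= 0 || me3$library_size <= 0) {
      stop("cannot normalize a track with library_size 0", call. = FALSE)
    }
    d1 <- d1 * (1e6 / me1$library_size)
    d3 <- d3 * (1e6 / me3$library_size)
  }
  values <- log2((d1 + pseudocount) / (d3 + pseudocount))
  new_ratio_track(me1$chrom, me1$chrom_length, me1$bin_width, values,
                  pseudocount)
}

#' Call enhancer regions from a log2 ratio track
#'
#' Finds maximal runs of consecutive bins with ratio strictly above
#' `threshold`; runs separated by at most `merge_gap` bp are merged, and
#' merged runs spanning fewer than `min_length` bp are discarded.
#' Coordinates are reported in base space (0-based half-open), with the
#' mean and maximum ratio over each region's bins.
#'
#' @param ratio A `ratio_track`, or a list of them (one per chromosome).
#' @param threshold Call bins with log2 ratio strictly above this
#'   (default 1.2).
#' @param min_length Minimum region span in bp after merging (default 1,
#'   the literal per-position rule; larger values suppress short noise
#'   excursions).
#' @param merge_gap Merge runs separated by at most this many bp
#'   (default 0).
#' @return A data.frame with columns `chrom`, `start0`, `end0`,
#'   `mean_ratio`, `max_ratio`, sorted and non-overlapping.
#' @export
call_enhancers <- function(ratio, threshold = 1.2, min_length = 1,
                           merge_gap = 0) {
  stopifnot(is.finite(threshold), min_length >= 1, merge_gap >= 0)
  if (inherits(ratio, "ratio_track")) ratio <- list(ratio)
  out <- lapply(ratio, function(rt) {
    hits <- rt$values > threshold
    rl <- S4Vectors::runLength(hits)
    rv <- S4Vectors::runValue(hits)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    ir <- IRanges::IRanges(start = starts[rv], end = ends[rv])
    # a gap of g bins spans g * bin_width bp; merge when that is <= merge_gap
    gap_bins <- floor(merge_gap / rt$bin_width)
    ir <- IRanges::reduce(ir, min.gapwidth = gap_bins + 1L)
    if (length(ir) == 0) {
      return(data.frame(chrom = character(0), start0 = integer(0),
                        end0 = integer(0), mean_ratio = numeric(0),
                        max_ratio = numeric(0)))
    }
    start0 <- (IRanges::start(ir) - 1L) * rt$bin_width
    end0 <- pmin(IRanges::end(ir) * rt$bin_width, rt$chrom_length)
    keep <- (end0 - start0) >= min_length
    ir <- ir[keep]
    if (length(ir) == 0) {
      return(data.frame(chrom = character(0), start0 = integer(0),
                        end0 = integer(0), mean_ratio = numeric(0),
                        max_ratio = numeric(0)))
    }
    v <- IRanges::Views(rt$values, IRanges::start(ir), IRanges::end(ir))
    data.frame(chrom = rt$chrom,
               start0 = start0[keep],
               end0 = end0[keep],
               mean_ratio = IRanges::viewMeans(v),
               max_ratio = IRanges::viewMaxs(v))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write called regions as BED3+2
#'
#' Columns: chrom, start, end, mean_ratio, max_ratio (no header).
#'
#' @param regions Region data.frame from [call_enhancers()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  out <- regions[, c("chrom", "start0", "end0", "mean_ratio", "max_ratio")]
  out$mean_ratio <- sprintf("%.6g", out$mean_ratio)
  out$max_ratio <- sprintf("%.6g", out$max_ratio)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read called regions back from BED3+2
#' @param path Path written by [write_regions_bed()].
#' @return A region data.frame (`chrom`, `start0`, `end0`, `mean_ratio`,
#'   `max_ratio`).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start0", "end0",
                                        "mean_ratio", "max_ratio"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "numeric"))
  df[order(df$chrom, df$start0), , drop = FALSE]
}

#' Export a ratio track as bedGraph
#'
#' One record per run of constant value, the standard compact encoding.
#'
#' @param ratio A `ratio_track` or list of them.
#' @param path Output bedGraph file.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(ratio, path) {
  if (inherits(ratio, "ratio_track")) ratio <- list(ratio)
  runs <- do.call(rbind, lapply(ratio, function(rt) {
    rl <- S4Vectors::runLength(rt$values)
    rv <- S4Vectors::runValue(rt$values)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    data.frame(chrom = rt$chrom,
               start = (starts - 1L) * rt$bin_width + 1L,
               end = pmin(ends * rt$bin_width, rt$chrom_length),
               score = as.numeric(rv))
  }))
  gr <- GenomicRanges::GRanges(runs$chrom,
                               IRanges::IRanges(runs$start, runs$end),
                               score = runs$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
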