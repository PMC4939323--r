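# Seeded synthetic-data generators: ChIP-seq read pileups with planted
# high-me1/low-me3 intervals, a pairwise LD graph around lead SNPs, and
# decoy SNPs kept clear of the planted signal. All randomness flows from
# the config seed, so a fixed config reproduces byte-identical tables.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#'
#' @param seed Integer RNG seed; a fixed config yields byte-identical
#'   outputs.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_enhancers Number of enhancer intervals to plant (when no
#'   explicit truth regions are supplied).
#' @param enhancer_length_range Length-2 vector, min/max planted interval
#'   length (bp).
#' @param me1_enrichment Fold-change of the H3K4me1 read rate inside
#'   planted intervals relative to background; must exceed 1.
#' @param me3_enrichment Fold-change of the H3K4me3 read rate inside
#'   planted intervals; at most 1 (enhancers are me3-depleted).
#' @param background_depth Mean per-base read coverage of the background,
#'   per track; read starts follow a Poisson process of rate
#'   `background_depth / read_length` per bp (times the enrichment inside
#'   planted intervals).
#' @param read_length Read length in bp.
#' @param n_decoy_snps Number of decoy SNPs to place in clear background.
#' @param n_leads Number of lead SNPs in the simulated LD graph.
#' @param proxies_per_lead Proxy records emitted per lead.
#' @param r2_distribution Length-2 vector `(low, high)`, uniform bounds
#'   for simulated r2 values; requires `low < high`.
#' @param windows Optional data.frame (`chrom`, `start0`, `end0`) of
#'   analysis windows; reads are emitted only inside them. `NULL` (the
#'   default) simulates whole chromosomes. Restricting to windows keeps
#'   desk-scale demos on real coordinates fast.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 200000L),
                       n_enhancers = 10L,
                       enhancer_length_range = c(800L, 1500L),
                       me1_enrichment = 8,
                       me3_enrichment = 1,
                       background_depth = 5,
                       read_length = 50L,
                       n_decoy_snps = 50L,
                       n_leads = 5L,
                       proxies_per_lead = 4L,
                       r2_distribution = c(0.5, 1.0),
                       windows = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1),
            n_enhancers >= 0,
            length(enhancer_length_range) == 2,
            enhancer_length_range[1] >= 1,
            enhancer_length_range[1] <= enhancer_length_range[2],
            background_depth > 0, read_length >= 1,
            n_decoy_snps >= 0, n_leads >= 0, proxies_per_lead >= 0)
  if (me1_enrichment <= 1) {
    stop("me1_enrichment must exceed 1 (planted intervals must be ",
         "me1-enriched)", call. = FALSE)
  }
  if (me3_enrichment > 1) {
    stop("me3_enrichment must be at most 1 inside planted intervals",
         call. = FALSE)
  }
  if (length(r2_distribution) != 2 ||
      r2_distribution[1] >= r2_distribution[2]) {
    stop("r2_distribution must be (low, high) with low < high",
         call. = FALSE)
  }
  if (r2_distribution[1] < 0 || r2_distribution[2] > 1) {
    stop("r2_distribution bounds must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(windows)) {
    stopifnot(all(c("chrom", "start0", "end0") %in% names(windows)),
              all(windows$chrom %in% names(chrom_lengths)),
              all(windows$start0 >= 0),
              all(windows$end0 <= chrom_lengths[windows$chrom]),
              all(windows$end0 > windows$start0))
  }
  structure(list(seed = as.integer(seed),
                 chrom_lengths = chrom_lengths,
                 n_enhancers = as.integer(n_enhancers),
                 enhancer_length_range = as.integer(enhancer_length_range),
                 me1_enrichment = me1_enrichment,
                 me3_enrichment = me3_enrichment,
                 background_depth = background_depth,
                 read_length = as.integer(read_length),
                 n_decoy_snps = as.integer(n_decoy_snps),
                 n_leads = as.integer(n_leads),
                 proxies_per_lead = as.integer(proxies_per_lead),
                 r2_distribution = r2_distribution,
                 windows = windows),
            class = "sim_config")
}

#' Simulate a pairwise LD table around lead SNPs
#'
#' Emits `proxies_per_lead` proxy records per lead, with r2 drawn
#' uniformly from `r2_distribution` and proxy coordinates uniform over the
#' simulated chromosomes. The truth record lists the proxies whose r2
#' strictly exceeds 0.8, the strong-LD convention downstream expansion
#' uses.
#'
#' @param config A [sim_config()].
#' @return A list: `ld` (LD table data.frame in the [load_ld_table()]
#'   dialect), `leads` (catalog-style data.frame of the simulated leads),
#'   and `truth` (character vector of proxy ids with r2 > 0.8).
#' @export
simulate_ld_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_leads * config$proxies_per_lead
  lead_ids <- sprintf("rsL%03d", seq_len(config$n_leads))
  chroms <- names(config$chrom_lengths)
  ld <- data.frame(
    lead_id = rep(lead_ids, each = config$proxies_per_lead),
    proxy_id = sprintf("rsP%04d", seq_len(n)),
    r2 = stats::runif(n, config$r2_distribution[1],
                      config$r2_distribution[2]),
    population = "SIM",
    proxy_chrom = sample(chroms, n, replace = TRUE,
                         prob = config$chrom_lengths / sum(config$chrom_lengths)),
    proxy_pos0 = NA_integer_)
  ld$proxy_pos0 <- as.integer(floor(stats::runif(
    n, 0, config$chrom_lengths[ld$proxy_chrom])))
  leads <- data.frame(snp_id = lead_ids,
                      p_value = 10^-stats::runif(config$n_leads, 6, 20),
                      chrom = sample(chroms, config$n_leads, replace = TRUE),
                      population = "SIM",
                      pmid = "0")
  list(ld = ld, leads = leads, truth = ld$proxy_id[ld$r2 > 0.8])
}

# Draw disjoint enhancer intervals within chromosome bounds.
place_enhancers <- function(config) {
  lens <- config$chrom_lengths
  if (config$n_enhancers == 0) {
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end0 = integer(0)))
  }
  widths <- sample(seq(config$enhancer_length_range[1],
                       config$enhancer_length_range[2]),
                   config$n_enhancers, replace = TRUE)
  chroms <- sample(names(lens), config$n_enhancers, replace = TRUE,
                   prob = lens / sum(lens))
  for (chr in unique(chroms)) {
    if (sum(widths[chroms == chr]) > lens[[chr]]) {
      stop("enhancer placement impossible: total planted length exceeds ",
           chr, call. = FALSE)
    }
  }
  levels <- names(lens)
  placed <- GenomicRanges::GRanges(factor(character(0), levels),
                                   IRanges::IRanges())
  for (i in seq_len(config$n_enhancers)) {
    for (attempt in 1:1000) {
      s <- floor(stats::runif(1, 0, lens[[chroms[i]]] - widths[i]))
      cand <- GenomicRanges::GRanges(factor(chroms[i], levels),
                                     IRanges::IRanges(s + 1, width = widths[i]))
      if (length(GenomicRanges::findOverlaps(cand, placed)) == 0) {
        placed <- c(placed, cand)
        break
      }
      if (attempt == 1000) {
        stop("enhancer placement impossible: could not find disjoint ",
             "position on ", chroms[i], call. = FALSE)
      }
    }
  }
  placed <- GenomicRanges::sort(placed)
  data.frame(chrom = as.character(GenomicRanges::seqnames(placed)),
             start0 = GenomicRanges::start(placed) - 1L,
             end0 = GenomicRanges::end(placed))
}

# Poisson read starts over [start0, end0) at `rate` starts per bp.
draw_reads <- function(chrom, start0, end0, rate, read_length, chrom_len) {
  n <- stats::rpois(1, (end0 - start0) * rate)
  if (n == 0) {
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end0 = integer(0)))
  }
  starts <- sort(as.integer(floor(stats::runif(n, start0, end0))))
  data.frame(chrom = chrom, start0 = starts,
             end0 = pmin(starts + read_length, chrom_len))
}

#' Simulate paired H3K4me1/H3K4me3 read alignments with planted enhancers
#'
#' Read starts follow a homogeneous Poisson process whose rate is
#' `background_depth / read_length` per bp in the background and that rate
#' times the mark's enrichment inside planted intervals, so the expected
#' per-base coverage is `background_depth` outside and
#' `background_depth * enrichment` inside. Reads have fixed length and are
#' clipped at chromosome ends.
#'
#' @param config A [sim_config()]. When `config$windows` is set, reads are
#'   only emitted inside those windows.
#' @param truth_regions Optional data.frame (`chrom`, `start0`, `end0`) of
#'   planted intervals; by default `n_enhancers` disjoint intervals are
#'   drawn from the config. Supplied regions must be disjoint and within
#'   chromosome bounds.
#' @return A list: `me1` and `me3` (read data.frames, `chrom`, `start0`,
#'   `end0`, sorted), and `truth_regions`.
#' @export
simulate_reads <- function(config, truth_regions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(truth_regions)) {
    truth_regions <- place_enhancers(config)
  } else {
    truth_regions <- truth_regions[order(truth_regions$chrom,
                                         truth_regions$start0), ,
                                   drop = FALSE]
    rownames(truth_regions) <- NULL
    validate_truth(truth_regions, config$chrom_lengths)
  }
  truth_gr <- df_to_granges(truth_regions)
  windows <- config$windows
  if (is.null(windows)) {
    windows <- data.frame(chrom = names(config$chrom_lengths),
                          start0 = 0L,
                          end0 = as.integer(config$chrom_lengths))
  }
  windows <- windows[order(windows$chrom, windows$start0), , drop = FALSE]
  win_gr <- GenomicRanges::reduce(df_to_granges(windows))
  base_rate <- config$background_depth / config$read_length
  tracks <- list(me1 = config$me1_enrichment, me3 = config$me3_enrichment)
  out <- lapply(tracks, function(enrich) {
    sig <- GenomicRanges::intersect(win_gr, truth_gr)
    bg <- GenomicRanges::setdiff(win_gr, truth_gr)
    segs <- rbind(granges_to_df(sig, rate = base_rate * enrich),
                  granges_to_df(bg, rate = base_rate))
    segs <- segs[order(segs$chrom, segs$start0), , drop = FALSE]
    reads <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      draw_reads(segs$chrom[i], segs$start0[i], segs$end0[i], segs$rate[i],
                 config$read_length,
                 config$chrom_lengths[[segs$chrom[i]]])
    }))
    reads <- reads[order(reads$chrom, reads$start0), , drop = FALSE]
    rownames(reads) <- NULL
    reads
  })
  list(me1 = out$me1, me3 = out$me3, truth_regions = truth_regions)
}

validate_truth <- function(truth, chrom_lengths) {
  if (nrow(truth) == 0) return(invisible(TRUE))
  stopifnot(all(truth$chrom %in% names(chrom_lengths)),
            all(truth$start0 >= 0),
            all(truth$end0 <= chrom_lengths[truth$chrom]),
            all(truth$end0 > truth$start0))
  gr <- df_to_granges(truth)
  if (length(GenomicRanges::reduce(gr)) != length(gr)) {
    stop("planted truth intervals must be pairwise disjoint", call. = FALSE)
  }
  invisible(TRUE)
}

df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start0 + 1L,
                                          end = df$end0))
}

granges_to_df <- function(gr, ...) {
  extra <- list(...)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr))
  for (nm in names(extra)) df[[nm]] <- rep(extra[[nm]], length.out = nrow(df))
  df
}

#' Place decoy SNPs in clear background
#'
#' Draws `n_decoy_snps` single-base loci inside the simulation windows but
#' at least `2 * read_length` bp away from every planted interval, so no
#' decoy can fall inside signal that bleeds past a planted edge.
#'
#' @param config A [sim_config()].
#' @param truth_regions Planted intervals to stay clear of.
#' @return A SNP-locus data.frame (`snp_id`, `chrom`, `start0`, `end0`,
#'   `strand`, `population`) with ids `decoy001`, `decoy002`, ...
#' @export
simulate_decoy_snps <- function(config, truth_regions) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  windows <- config$windows
  if (is.null(windows)) {
    windows <- data.frame(chrom = names(config$chrom_lengths),
                          start0 = 0L,
                          end0 = as.integer(config$chrom_lengths))
  }
  win_gr <- GenomicRanges::reduce(df_to_granges(windows))
  clearance <- 2L * config$read_length
  if (nrow(truth_regions) > 0) {
    padded <- df_to_granges(truth_regions)
    padded <- GenomicRanges::resize(padded,
                                    GenomicRanges::width(padded) + 2L * clearance,
                                    fix = "center")
    allowed <- GenomicRanges::setdiff(win_gr, padded)
  } else {
    allowed <- win_gr
  }
  widths <- GenomicRanges::width(allowed)
  if (sum(widths) < config$n_decoy_snps) {
    stop("not enough clear background to place decoy SNPs", call. = FALSE)
  }
  # index uniformly into the concatenated allowed space
  idx <- sort(sample.int(sum(widths), config$n_decoy_snps))
  seg <- findInterval(idx - 1L, cumsum(c(0L, widths)),
                      rightmost.closed = FALSE)
  offset <- idx - 1L - cumsum(c(0L, widths))[seg]
  pos0 <- GenomicRanges::start(allowed)[seg] - 1L + offset
  data.frame(snp_id = sprintf("decoy%03d", seq_len(config$n_decoy_snps)),
             chrom = as.character(GenomicRanges::seqnames(allowed))[seg],
             start0 = as.integer(pos0),
             end0 = as.integer(pos0) + 1L,
             strand = ".",
             population = "SIM")
}

#' Write simulated reads to the TSV dialect (and optionally BAM)
#'
#' Writes `me1.tsv`, `me3.tsv` and `truth.bed` under `dir`; with
#' `bam = TRUE` also writes coordinate-sorted, indexed `me1.bam` /
#' `me3.bam` whose headers carry the config's chromosome lengths.
#'
#' @param sim Result of [simulate_reads()].
#' @param config The [sim_config()] used to generate `sim`.
#' @param dir Output directory (created if needed).
#' @param bam Also emit BAM alignments (default `FALSE`).
#' @return Invisibly, a named vector of the files written.
#' @export
write_simulated_reads <- function(sim, config, dir, bam = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(me1 = file.path(dir, "me1.tsv"),
             me3 = file.path(dir, "me3.tsv"),
             truth = file.path(dir, "truth.bed"))
  write_tsv(sim$me1, paths[["me1"]])
  write_tsv(sim$me3, paths[["me3"]])
  utils::write.table(sim$truth_regions[, c("chrom", "start0", "end0")],
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (bam) {
    for (track in c("me1", "me3")) {
      bam_path <- write_reads_bam(sim[[track]], config$chrom_lengths,
                                  file.path(dir, paste0(track, ".bam")))
      paths[[paste0(track, "_bam")]] <- bam_path
    }
  }
  invisible(paths)
}

#' Write read intervals as a BAM file
#'
#' Emits a SAM text file (header from `chrom_lengths`, one unpaired mapped
#' record per read) and converts it to a sorted, indexed BAM.
#'
#' @param reads Read data.frame (`chrom`, `start0`, `end0`).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output BAM path.
#' @return Invisibly, `path`.
#' @export
write_reads_bam <- function(reads, chrom_lengths, path) {
  sam <- sub("\\.bam$", ".sam", path)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), reads$chrom, reads$start0 + 1L,
                  reads$end0 - reads$start0)
  writeLines(c(header, body), sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(sam)
  invisible(path)
}
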