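# Fixture-backed demonstration run: simulated coverage tracks whose
# planted intervals cover the packaged enhancer-SNP loci, a synthetic LD
# table tying every candidate to a packaged lead, and the packaged
# annotation tables. Serves as the executable end-to-end example and the
# basis of the acceptance checks.

#' Build the demo input files
#'
#' Writes the packaged catalog, SNP loci plus simulated decoys, a
#' synthetic LD table linking each of them to a packaged lead
#' (r2 in 0.85-0.99), simulated H3K4me1/H3K4me3 read tracks with planted
#' signal over every packaged locus, chromosome sizes, and the packaged
#' annotation tables.
#'
#' @param dir Directory to create the inputs in.
#' @param seed Integer seed driving the simulation.
#' @param n_decoys Number of clear-background decoy SNPs (default 50).
#' @param background_depth Mean background coverage per track (default 5).
#' @param me1_enrichment H3K4me1 fold-enrichment in planted intervals
#'   (default 8).
#' @param bam Emit the simulated reads as BAM instead of the TSV dialect.
#' @return A [pipeline_config()] pointing at the generated files, with
#'   `min_length = 200` (see the package vignette for why the demo uses a
#'   minimum region span).
#' @export
build_demo_inputs <- function(dir, seed = 1L, n_decoys = 50L,
                              background_depth = 5, me1_enrichment = 8,
                              bam = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pad <- 600L
  loci <- make_snp_fixture()

  truth_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start0 + 1L - pad,
                                 loci$end0 + pad)))
  truth <- granges_to_df(GenomicRanges::sort(truth_gr))

  # Background breadth per chromosome. Genome-wide, enhancers are a tiny
  # fraction of the territory, so the two mark libraries are nearly equal
  # in size; the windowed demo reproduces that by simulating a wide
  # background-only window on every chromosome (which also hosts the
  # decoys). Too little background would inflate the me1 library relative
  # to me3 and bias the reads-per-million ratio downward inside planted
  # regions.
  bg_width <- 500000L
  chroms <- sort(unique(truth$chrom))
  last_end <- vapply(chroms, function(c) max(truth$end0[truth$chrom == c]),
                     numeric(1))
  bg_windows <- data.frame(
    chrom = chroms,
    start0 = as.integer(last_end + 10000L),
    end0 = as.integer(last_end + 10000L + bg_width))
  # decoys live in their own windows, 10 kb past the sequenced background:
  # candidate SNPs far from any enhancer, in territory the coverage rule
  # sees as flat (zero) signal
  decoy_windows <- data.frame(
    chrom = chroms,
    start0 = as.integer(bg_windows$end0 + 10000L),
    end0 = as.integer(bg_windows$end0 + 110000L))
  chrom_lengths <- stats::setNames(
    as.integer(decoy_windows$end0 + 10000L), chroms)

  sig_windows <- granges_to_df(GenomicRanges::reduce(GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start0 + 1L - 2000L,
                                  truth$end0 + 2000L))))
  windows <- rbind(sig_windows, bg_windows)

  cfg <- sim_config(seed = seed, chrom_lengths = chrom_lengths,
                    me1_enrichment = me1_enrichment, me3_enrichment = 1,
                    background_depth = background_depth, read_length = 50L,
                    n_decoy_snps = n_decoys, windows = windows)
  sim <- simulate_reads(cfg, truth_regions = truth)
  read_paths <- write_simulated_reads(sim, cfg, dir, bam = bam)

  decoy_cfg <- cfg
  decoy_cfg$windows <- decoy_windows
  decoys <- simulate_decoy_snps(decoy_cfg, truth)
  decoys$population <- rep(c("CHB", "JPT"), length.out = nrow(decoys))

  snps <- rbind(loci, decoys)
  snp_bed <- file.path(dir, "candidate_snps.bed")
  write_snp_bed(snps, snp_bed)

  catalog <- make_gwas_fixture()
  set.seed(cfg$seed + 7L)
  lead_for <- vapply(seq_len(nrow(snps)), function(i) {
    pool <- catalog$snp_id[catalog$population == snps$population[i] &
                             catalog$snp_id != snps$snp_id[i]]
    pool[1]
  }, character(1))
  ld <- data.frame(lead_id = lead_for,
                   proxy_id = snps$snp_id,
                   r2 = round(stats::runif(nrow(snps), 0.85, 0.99), 4),
                   population = snps$population,
                   proxy_chrom = snps$chrom,
                   proxy_pos0 = snps$start0)
  ld_path <- file.path(dir, "ld_table.tsv")
  write_ld_table(ld, ld_path)

  sizes_path <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(chrom_lengths, sizes_path)
  fixture_paths <- write_fixture_files(dir)

  pipeline_config(
    catalog = fixture_paths[["catalog"]],
    ld = ld_path,
    me1_reads = if (bam) read_paths[["me1_bam"]] else read_paths[["me1"]],
    me3_reads = if (bam) read_paths[["me3_bam"]] else read_paths[["me3"]],
    chrom_sizes = sizes_path,
    snp_bed = snp_bed,
    annotations = fixture_paths[["annotations"]],
    gene_links = fixture_paths[["gene_links"]],
    out_dir = file.path(dir, "out"),
    min_length = 100,
    seed = seed)
}

#' Run the packaged end-to-end demo
#'
#' Builds the demo inputs under `dir` and runs the full pipeline. With
#' the defaults the manifest counts are 45 leads, 22 enhancer SNPs, 14
#' regulatory and 9 distal.
#'
#' @inheritParams build_demo_inputs
#' @param dir Working directory for inputs and outputs (default a
#'   tempdir).
#' @return The run manifest (see [run_pipeline()]); the pipeline config
#'   is attached as attribute `config`.
#' @export
demo_pipeline <- function(dir = tempfile("enhsnp_demo_"), seed = 1L,
                          n_decoys = 50L, background_depth = 5,
                          me1_enrichment = 8, bam = FALSE) {
  config <- build_demo_inputs(dir, seed = seed, n_decoys = n_decoys,
                              background_depth = background_depth,
                              me1_enrichment = me1_enrichment, bam = bam)
  manifest <- run_pipeline(config)
  attr(manifest, "config") <- config
  manifest
}
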