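test_that("packaged catalog has the expected shape and content", {
  cat45 <- make_gwas_fixture()
  expect_equal(nrow(cat45), 45)
  expect_equal(sum(cat45$population == "CHB"), 26)
  expect_equal(sum(cat45$population == "JPT"), 19)
  row <- cat45[cat45$snp_id == "rs17401966", ]
  expect_equal(row$p_value, 1.2e-19)
  expect_equal(row$chrom, "chr1")
  expect_equal(row$population, "CHB")
  expect_equal(row$pmid, "20676096")
  expect_false(anyDuplicated(cat45$snp_id) > 0)
})

test_that("packaged SNP loci are 22 single-base intervals", {
  loci <- make_snp_fixture()
  expect_equal(nrow(loci), 22)
  expect_true(all(loci$end0 - loci$start0 == 1))
  row <- loci[loci$snp_id == "rs12751375", ]
  expect_equal(row$chrom, "chr1")
  expect_equal(row$start0, 10291873)
  expect_equal(row$strand, "+")
  expect_equal(row$population, "CHB")
})

test_that("packaged annotations carry 14 records, 9 distal, with gene links", {
  fix <- make_annotation_fixture()
  expect_equal(nrow(fix$annotations), 14)
  expect_equal(sum(fix$annotations$is_distal), 9)
  expect_true(all(fix$annotations$is_regulatory))
  r <- fix$annotations[fix$annotations$snp_id == "rs12751375", ]
  expect_false(r$is_distal)
  genes <- fix$gene_links$gene_symbol[fix$gene_links$snp_id == "rs9494257"]
  expect_setequal(genes, c("BCLAF1", "AHI1", "LINC00271"))
  expect_equal(sum(fix$gene_links$snp_id == "rs5994449"), 8)
  # every distal-flagged SNP has at least one distal gene link
  distal <- fix$annotations$snp_id[fix$annotations$is_distal]
  expect_true(all(distal %in% fix$gene_links$snp_id))
})

test_that("fixture tables round-trip through their parsers without loss", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  expect_equal(load_catalog(paths[["catalog"]]), make_gwas_fixture())
  loci <- load_snp_bed(paths[["snps"]])
  fix <- make_snp_fixture()
  expect_equal(loci$snp_id, fix$snp_id)
  expect_equal(loci$pos0, fix$start0)
  expect_equal(loci$strand, fix$strand)
  expect_equal(loci$population, fix$population)
  ann <- load_annotations(paths[["annotations"]], paths[["gene_links"]])
  ref <- make_annotation_fixture()
  expect_equal(ann$annotations, ref$annotations)
  expect_equal(ann$gene_links, ref$gene_links)
})

test_that("simulated LD tables follow the configured r2 bounds and truth rule", {
  cfg <- sim_config(seed = 11, n_leads = 2, proxies_per_lead = 3,
                    r2_distribution = c(0.9, 1.0))
  sim <- simulate_ld_table(cfg)
  expect_equal(nrow(sim$ld), 6)
  expect_setequal(sim$truth, sim$ld$proxy_id)

  cfg_low <- sim_config(seed = 11, n_leads = 2, proxies_per_lead = 3,
                        r2_distribution = c(0.0, 0.5))
  expect_length(simulate_ld_table(cfg_low)$truth, 0)

  expect_error(sim_config(r2_distribution = c(0.9, 0.9)), "low < high")

  again <- simulate_ld_table(cfg)
  expect_identical(sim, again)
})

test_that("simulated read depth matches the configured law", {
  cfg <- sim_config(seed = 42, chrom_lengths = c(chrA = 60000L),
                    n_enhancers = 4, enhancer_length_range = c(1000, 1500),
                    me1_enrichment = 8, me3_enrichment = 1,
                    background_depth = 2, read_length = 50)
  sim <- simulate_reads(cfg)
  truth <- sim$truth_regions
  expect_equal(nrow(truth), 4)
  # independent oracle: per-base overlap counting, averaged over intervals
  d_me1 <- oracle_depths(sim$me1, "chrA", 60000L)
  d_me3 <- oracle_depths(sim$me3, "chrA", 60000L)
  inside <- unlist(mapply(function(s, e) (s + 1L):e,
                          truth$start0, truth$end0, SIMPLIFY = FALSE))
  outside <- setdiff(seq_len(60000L), inside)
  total_len <- sum(truth$end0 - truth$start0)
  # mean depth ~ Poisson read count * read_length / interval length
  se_in <- 50 * sqrt(16 / 50 * total_len) / total_len
  expect_lt(abs(mean(d_me1[inside]) - 16), 3 * se_in)
  se_out <- 50 * sqrt(2 / 50 * length(outside)) / length(outside)
  expect_lt(abs(mean(d_me1[outside]) - 2), 3 * se_out + 0.1)
  expect_lt(abs(mean(d_me3[inside]) - 2), 1)

  again <- simulate_reads(cfg)
  expect_identical(sim, again)
})

test_that("degenerate and invalid simulation configs are handled", {
  cfg0 <- sim_config(seed = 5, n_enhancers = 0)
  expect_equal(nrow(simulate_reads(cfg0)$truth_regions), 0)
  expect_error(sim_config(me1_enrichment = 1), "me1_enrichment")
  expect_error(sim_config(me3_enrichment = 1.5), "me3_enrichment")
  # planting more enhancer bases than the chromosome holds is impossible
  cfg_big <- sim_config(seed = 5, chrom_lengths = c(chr1 = 5000L),
                        n_enhancers = 10,
                        enhancer_length_range = c(900, 1000))
  expect_error(simulate_reads(cfg_big), "placement impossible")
})

test_that("planted truth respects chromosome bounds and decoys stay clear", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 50000L, chr2 = 30000L),
                    n_enhancers = 8, enhancer_length_range = c(500, 900),
                    n_decoy_snps = 40)
  sim <- simulate_reads(cfg)
  truth <- sim$truth_regions
  expect_true(all(truth$start0 >= 0))
  expect_true(all(truth$end0 <= cfg$chrom_lengths[truth$chrom]))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start0 + 1, truth$end0))
  expect_equal(length(GenomicRanges::reduce(tg)), nrow(truth))
  decoys <- simulate_decoy_snps(cfg, truth)
  expect_equal(nrow(decoys), 40)
  dg <- GenomicRanges::GRanges(decoys$chrom,
                               IRanges::IRanges(decoys$start0 + 1,
                                                decoys$end0))
  pad <- GenomicRanges::resize(tg, GenomicRanges::width(tg) +
                                 4L * cfg$read_length, fix = "center")
  expect_equal(length(GenomicRanges::findOverlaps(dg, pad)), 0)
})

test_that("simulated read files are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 20000L),
                    n_enhancers = 2, enhancer_length_range = c(400, 600))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_reads(simulate_reads(cfg), cfg, d1)
  write_simulated_reads(simulate_reads(cfg), cfg, d2)
  for (f in c("me1.tsv", "me3.tsv", "truth.bed")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("shipped extdata copies match the in-code fixture tables", {
  dir <- system.file("extdata", package = "enhsnp")
  fresh <- withr::local_tempdir()
  paths <- write_fixture_files(fresh)
  for (f in basename(paths)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(fresh, f))),
                     label = f)
  }
})
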