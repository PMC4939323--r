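cov1_of <- function(reads, len = 30L, chrom = "chr1", bw = 1) {
  compute_coverage(reads, stats::setNames(len, chrom), bin_width = bw)[[chrom]]
}

test_that("per-base coverage counts reads covering each position", {
  one <- data.frame(chrom = "chr1", start0 = 10L, end0 = 20L)
  trk <- cov1_of(one)
  d <- as.integer(trk$depths)
  expect_equal(d[11:20], rep(1L, 10))
  expect_equal(sum(d), 10)
  expect_equal(trk$library_size, 1)
  # additivity: duplicated reads double the depth
  two <- rbind(one, one)
  expect_equal(as.integer(cov1_of(two)$depths), 2L * d)
})

test_that("coverage clips overhanging reads and rejects unknown chromosomes", {
  over <- data.frame(chrom = "chr1", start0 = 25L, end0 = 40L)
  expect_warning(trk <- cov1_of(over), "clipped")
  expect_equal(sum(as.integer(trk$depths)), 5)
  bad <- data.frame(chrom = "chrZ", start0 = 0L, end0 = 5L)
  expect_error(cov1_of(bad), "unknown chromosome")
})

test_that("binned coverage counts reads overlapping any base of the bin", {
  # read [4,6) touches bins [0,5) and [5,10)
  r <- data.frame(chrom = "chr1", start0 = 4L, end0 = 6L)
  trk <- cov1_of(r, len = 20L, bw = 5)
  expect_equal(as.integer(trk$depths), c(1L, 1L, 0L, 0L))
})

test_that("coverage matches the brute-force per-base oracle", {
  set.seed(501)
  reads <- random_reads(500, 2000L)
  trk <- cov1_of(reads, len = 2000L)
  expect_equal(as.integer(trk$depths), oracle_depths(reads, "chr1", 2000L))
})

test_that("coverage conservation: total depth equals total read bases", {
  set.seed(502)
  reads <- random_reads(300, 1000L, read_length = 25)
  reads$end0 <- pmin(reads$end0, 1000L)
  trk <- cov1_of(reads, len = 1000L)
  expect_equal(sum(as.numeric(trk$depths)), sum(reads$end0 - reads$start0))
})

test_that("log2 ratio arithmetic is exact on constant tracks", {
  me1 <- cov1_of(data.frame(chrom = "chr1", start0 = rep(0L, 4),
                            end0 = rep(30L, 4)))
  me3 <- cov1_of(data.frame(chrom = "chr1", start0 = 0L, end0 = 30L))
  rt <- ratio_track(me1, me3, pseudocount = 1, normalize = FALSE)
  expect_equal(unique(as.numeric(rt$values)), log2(5 / 2))
  # symmetry: identical tracks give ratio 0 for any pseudocount
  rt0 <- ratio_track(me1, me1, pseudocount = 0.7, normalize = FALSE)
  expect_equal(unique(as.numeric(rt0$values)), 0)
  expect_error(ratio_track(me1, me3, pseudocount = 0), "pseudocount")
})

test_that("normalized ratio matches an elementwise recomputation oracle", {
  set.seed(503)
  me1 <- cov1_of(random_reads(200, 500L), len = 500L)
  me3 <- cov1_of(random_reads(150, 500L), len = 500L)
  rt <- ratio_track(me1, me3, pseudocount = 1, normalize = TRUE)
  d1 <- as.numeric(me1$depths) * 1e6 / me1$library_size
  d3 <- as.numeric(me3$depths) * 1e6 / me3$library_size
  expect_equal(as.numeric(rt$values), log2((d1 + 1) / (d3 + 1)))
})

test_that("run calling implements threshold, gap and length semantics", {
  r <- call_enhancers(make_ratio(c(0, 2, 2, 0)), threshold = 1.2,
                      min_length = 1, merge_gap = 0)
  expect_equal(r$start0, 1)
  expect_equal(r$end0, 3)
  expect_equal(r$mean_ratio, 2)
  # gap semantics
  split2 <- call_enhancers(make_ratio(c(2, 0, 2)), 1.2, 1, merge_gap = 0)
  expect_equal(nrow(split2), 2)
  merged <- call_enhancers(make_ratio(c(2, 0, 2)), 1.2, 1, merge_gap = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end0 - merged$start0, 3)
  # strict threshold: values equal to the cutoff are not called
  expect_equal(nrow(call_enhancers(make_ratio(c(1.2, 1.2)), 1.2, 1, 0)), 0)
  # min_length discards short merged runs
  expect_equal(nrow(call_enhancers(make_ratio(c(0, 3, 0)), 1.2, 2, 0)), 0)
})

test_that("run calling equals the positional-scan oracle on random tracks", {
  set.seed(504)
  for (rep in 1:200) {
    values <- round(stats::runif(sample(5:60, 1), -3, 3), 2)
    thr <- stats::runif(1, -2, 2)
    ml <- sample(1:4, 1)
    mg <- sample(0:3, 1)
    got <- call_enhancers(make_ratio(values), thr, ml, mg)
    want <- oracle_call_runs(values, thr, ml, mg)
    expect_equal(got$start0, want$start0)
    expect_equal(got$end0, want$end0)
  }
})

test_that("called bases shrink as the threshold rises and stay nested", {
  set.seed(505)
  values <- stats::runif(400, -3, 3)
  prev <- NULL
  for (thr in c(-1, 0, 1, 2)) {
    regs <- call_enhancers(make_ratio(values), thr, 1, 0)
    bases <- unlist(mapply(function(s, e) if (e > s) (s + 1):e else NULL,
                           regs$start0, regs$end0, SIMPLIFY = FALSE))
    if (!is.null(prev)) expect_true(all(bases %in% prev))
    prev <- bases
  }
})

test_that("planted enhancers are recovered from simulated coverage", {
  cfg <- sim_config(seed = 314, chrom_lengths = c(chr1 = 400000L),
                    n_enhancers = 6, enhancer_length_range = c(900, 1400),
                    me1_enrichment = 8, me3_enrichment = 1,
                    background_depth = 5, read_length = 50)
  sim <- simulate_reads(cfg)
  cl <- cfg$chrom_lengths
  me1 <- compute_coverage(sim$me1, cl)[["chr1"]]
  me3 <- compute_coverage(sim$me3, cl)[["chr1"]]
  rt <- ratio_track(me1, me3, pseudocount = 1, normalize = TRUE)
  regs <- call_enhancers(rt, threshold = 1.2, min_length = 100)
  truth <- sim$truth_regions
  tg <- IRanges::IRanges(truth$start0 + 1, truth$end0)
  rg <- IRanges::IRanges(regs$start0 + 1, regs$end0)
  covered <- sum(IRanges::width(IRanges::intersect(rg, tg)))
  expect_gte(covered / sum(IRanges::width(tg)), 0.90)
  bg_called <- sum(IRanges::width(IRanges::setdiff(rg, tg)))
  bg_total <- 400000 - sum(IRanges::width(tg))
  expect_lte(bg_called / bg_total, 0.01)
})

test_that("BAM and TSV encodings of the same reads give identical coverage", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 20000L, chr2 = 15000L),
                    n_enhancers = 3, enhancer_length_range = c(300, 600))
  sim <- simulate_reads(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_reads(sim, cfg, dir, bam = TRUE)
  via_tsv <- compute_coverage(load_reads(paths[["me1"]]), cfg$chrom_lengths)
  via_bam <- compute_coverage(load_reads(paths[["me1_bam"]]),
                              cfg$chrom_lengths)
  for (chr in names(cfg$chrom_lengths)) {
    expect_identical(as.integer(via_tsv[[chr]]$depths),
                     as.integer(via_bam[[chr]]$depths))
    expect_equal(via_tsv[[chr]]$library_size, via_bam[[chr]]$library_size)
  }
})
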