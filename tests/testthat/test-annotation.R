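fixture_paths <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_fixture_files(dir)
}

test_that("annotation loading merges tables and checks consistency", {
  p <- fixture_paths()
  ann <- load_annotations(p[["annotations"]], p[["gene_links"]])
  expect_s3_class(ann, "regulatory_annotations")
  expect_equal(nrow(ann$annotations), 14)
  expect_equal(sum(ann$annotations$is_distal), 9)
  expect_equal(sum(ann$gene_links$snp_id == "rs5994449"), 8)

  # gene link for an unknown SNP is an error
  links <- make_annotation_fixture()$gene_links
  links$snp_id[1] <- "rs0000000"
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(links, bad, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_annotations(p[["annotations"]], bad),
               "absent from the annotation table")

  # a distal flag without gene links only warns
  empty <- tempfile(fileext = ".tsv")
  writeLines("snp_id\tgene_symbol\tensembl_id\tregulation_type", empty)
  expect_warning(load_annotations(p[["annotations"]], empty),
                 "distal flag without")
})

test_that("an all-non-distal table loads cleanly with empty gene links", {
  dir <- withr::local_tempdir()
  ann <- make_annotation_fixture()$annotations
  ann$is_distal <- FALSE
  links <- make_annotation_fixture()$gene_links[0, ]
  paths <- file.path(dir, c("a.tsv", "g.tsv"))
  write_annotations(ann, links, paths[1], paths[2])
  got <- load_annotations(paths[1], paths[2])
  expect_equal(sum(got$annotations$is_distal), 0)
  expect_equal(nrow(got$gene_links), 0)
})

test_that("validation counts regulatory and distal evidence", {
  ann <- make_annotation_fixture()
  s <- validate_snps(make_snp_fixture(), ann)
  expect_equal(s$n_input, 22)
  expect_equal(s$n_annotated, 14)
  expect_equal(s$n_regulatory, 14)
  expect_equal(s$n_distal, 9)
  tab <- table(s$per_snp$status)
  expect_equal(unname(tab[["regulatory-distal"]]), 9)
  expect_equal(unname(tab[["regulatory"]]), 5)
  expect_equal(unname(tab[["unannotated"]]), 8)

  empty <- validate_snps(make_snp_fixture()[0, ], ann)
  expect_equal(empty$n_input, 0)
  expect_equal(empty$n_distal, 0)

  lone <- validate_snps(data.frame(snp_id = "rs404"), ann)
  expect_equal(lone$n_annotated, 0)
  expect_equal(lone$per_snp$status, "unannotated")
})

test_that("the count chain holds on random subsets and any input order", {
  ann <- make_annotation_fixture()
  pool <- c(make_snp_fixture()$snp_id, sprintf("fake%02d", 1:10))
  set.seed(707)
  for (rep in 1:25) {
    ids <- sample(pool, sample.int(length(pool), 1))
    s <- validate_snps(data.frame(snp_id = ids), ann)
    expect_lte(s$n_distal, s$n_regulatory)
    expect_lte(s$n_regulatory, s$n_annotated)
    expect_lte(s$n_annotated, s$n_input)
    shuffled <- validate_snps(data.frame(snp_id = sample(ids)), ann)
    expect_equal(shuffled[c("n_input", "n_annotated", "n_regulatory",
                            "n_distal")],
                 s[c("n_input", "n_annotated", "n_regulatory", "n_distal")])
  }
})

test_that("reports are self-consistent with their summary", {
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  ann <- load_annotations(p[["annotations"]], p[["gene_links"]])
  s <- validate_snps(make_snp_fixture(), ann)
  files <- write_validation_report(s, ann, file.path(dir, "rep"))
  tsv <- utils::read.delim(files[["tsv"]])
  expect_equal(nrow(tsv), s$n_input)
  expect_equal(sum(tsv$status %in% c("regulatory", "regulatory-distal")),
               s$n_regulatory)
  expect_equal(sum(tsv$status == "regulatory-distal"), s$n_distal)
  genes <- tsv$target_genes[tsv$snp_id == "rs9494257"]
  expect_match(genes, "BCLAF1")
  expect_match(genes, "AHI1")
  expect_match(genes, "LINC00271")
  txt <- readLines(files[["text"]])
  expect_true(any(grepl(paste0("regulatory:\\s+", s$n_regulatory), txt)))

  empty <- validate_snps(data.frame(snp_id = character(0)), ann)
  files0 <- write_validation_report(empty, ann, file.path(dir, "rep0"))
  expect_equal(nrow(utils::read.delim(files0[["tsv"]])), 0)
})

test_that("multi-valued cells split into label lists", {
  got <- split_states(c("Enhancers; weak transcription", "n/a", ""))
  expect_equal(got[[1]], c("Enhancers", "weak transcription"))
  expect_length(got[[2]], 0)
  expect_length(got[[3]], 0)
})
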