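# Packaged reference tables for the liver-cancer (HepG2) use case.
# These are the canonical in-code instances; the TSV copies under
# inst/extdata/ are written by write_fixture_files() and must stay in sync
# (round-trip tested).

#' GWAS lead-SNP catalog fixture
#'
#' Returns the packaged catalog of 45 liver cancer-associated lead SNPs
#' (rsID, association p-value, chromosome, study population, PubMed id):
#' 26 from the CHB cohort and 19 from JPT. All p-values are below 1e-5.
#'
#' @return A data.frame with columns `snp_id`, `p_value`, `chrom`,
#'   `population`, `pmid`. Chromosome labels carry the `chr` prefix.
#' @export
#' @examples
#' cat45 <- make_gwas_fixture()
#' table(cat45$population)
make_gwas_fixture <- function() {
  txt <- "
rs17401966 1.20e-19 1 CHB 20676096
rs1249458 8.30e-06 2 CHB 22807686
rs1714259 1.10e-06 2 CHB 22807686
rs2396470 5.10e-07 2 CHB 20676096
rs7424161 8.80e-06 2 CHB 22807686
rs7574865 1.70e-11 2 CHB 23242368
rs3905886 3.70e-06 3 CHB 22807686
rs1073547 6.80e-06 4 CHB 22807686
rs17081345 3.70e-07 6 CHB 20676096
rs9272105 3.30e-23 6 CHB 22807686
rs9275319 8.70e-19 6 CHB 23242368
rs9494257 1.10e-14 6 CHB 20676096
rs12682266 6.70e-06 8 CHB 22174901
rs1573266 7.40e-06 8 CHB 22174901
rs2275959 6.40e-06 8 CHB 22174901
rs7821974 7.00e-06 8 CHB 22174901
rs7898005 7.00e-08 10 CHB 20676096
rs10160758 6.00e-06 11 CHB 22807686
rs10896464 6.50e-06 11 CHB 22807686
rs2611145 9.30e-06 11 CHB 22174901
rs3825023 3.10e-06 11 CHB 22807686
rs7119426 3.50e-06 11 CHB 22807686
rs402071 8.60e-06 19 CHB 22807686
rs3092194 4.40e-06 20 CHB 22807686
rs368007 9.90e-06 20 CHB 22807686
rs455804 4.40e-10 21 CHB 22807686
rs1980215 2.30e-06 3 JPT 21499248
rs2596542 4.20e-13 6 JPT 21499248
rs9275572 1.40e-09 6 JPT 21499248
rs1568658 6.90e-06 7 JPT 21499248
rs952656 2.80e-06 8 JPT 21499248
rs4363614 4.20e-07 11 JPT 21499248
rs1957496 4.60e-06 14 JPT 21499248
rs8019534 3.90e-06 14 JPT 21499248
rs1794304 3.60e-06 16 JPT 21725309
rs2208456 3.80e-06 20 JPT 21499248
rs1012068 1.30e-14 22 JPT 21725309
rs11703779 4.20e-06 22 JPT 21725309
rs4820994 3.00e-06 22 JPT 21725309
rs4820996 4.20e-06 22 JPT 21725309
rs5753816 4.90e-06 22 JPT 21725309
rs5753818 9.40e-06 22 JPT 21725309
rs5998152 1.20e-07 22 JPT 21725309
rs7287054 3.80e-06 22 JPT 21725309
rs737084 5.90e-06 22 JPT 21725309"
  df <- utils::read.table(text = txt, header = FALSE,
                          col.names = c("snp_id", "p_value", "chrom",
                                        "population", "pmid"),
                          colClasses = c("character", "numeric", "character",
                                         "character", "character"))
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Predicted enhancer-SNP locus fixture
#'
#' The 22 packaged enhancer-SNP loci (single-nucleotide intervals in 0-based
#' half-open coordinates) with strand and study population.
#'
#' @return A data.frame with columns `snp_id`, `chrom`, `start0`, `end0`,
#'   `strand`, `population`; every row satisfies `end0 == start0 + 1`.
#' @export
make_snp_fixture <- function() {
  txt <- "
rs12751375 chr1 10291873 10291874 + CHB
rs6700866 chr1 10306037 10306038 + CHB
rs9494257 chr6 135827471 135827472 + CHB
rs17064474 chr6 135680137 135680138 + CHB
rs17721919 chr6 135748923 135748924 + CHB
rs17721931 chr6 135749377 135749378 + CHB
rs6903949 chr6 135821065 135821066 + CHB
rs6996881 chr8 37407919 37407920 + CHB
rs4739519 chr8 37412858 37412859 + CHB
rs6988263 chr8 37414659 37414660 + CHB
rs12156293 chr8 37419921 37419922 + CHB
rs6928810 chr6 31410523 31410524 + JPT
rs3869132 chr6 31410947 31410948 - JPT
rs2596562 chr6 31354594 31354595 - JPT
rs2523475 chr6 31361709 31361710 - JPT
rs2523467 chr6 31362929 31362930 - JPT
rs9501387 chr6 31364458 31364459 + JPT
rs1568658 chr7 29141557 29141558 - JPT
rs1794304 chr16 12625394 12625395 + JPT
rs5994449 chr22 32304178 32304179 + JPT
rs5753816 chr22 32312841 32312842 + JPT
rs5749339 chr22 32315734 32315735 + JPT"
  utils::read.table(text = txt, header = FALSE,
                    col.names = c("snp_id", "chrom", "start0", "end0",
                                  "strand", "population"),
                    colClasses = c("character", "character", "integer",
                                   "integer", "character", "character"))
}

# Regulatory-annotation fixture: one row per annotated SNP. Multi-valued
# fields use "; " as the within-cell separator; "n/a" means none recorded.
.annotation_table <- function() {
  states <- c(
    rs12751375 = "Inactive region",
    rs6700866  = "Weak transcription; ZNF genes and repeats; strong transcription; enhancers",
    rs9494257  = "Enhancers; flanking active TSS; weak transcription",
    rs17064474 = "Weak transcription; active TSS; flanking active TSS; enhancers",
    rs17721919 = "Weak transcription",
    rs17721931 = "Weak transcription",
    rs6903949  = "Weak transcription; enhancers",
    rs6996881  = "Weak transcription; enhancers",
    rs4739519  = "Enhancers; weak transcription",
    rs6988263  = "Enhancers; weak transcription; genic enhancers; bivalent enhancer; flanking active TSS",
    rs12156293 = "Enhancers; weak transcription; bivalent enhancer; genic enhancers",
    rs1568658  = "Weak transcription; enhancers; strong transcription",
    rs5994449  = "Weak transcription; strong transcription; ZNF genes and repeats",
    rs5753816  = "Weak transcription; enhancers; flanking active TSS"
  )
  distal <- c("rs9494257", "rs6903949", "rs6996881", "rs4739519",
              "rs6988263", "rs12156293", "rs1568658", "rs5994449",
              "rs5753816")
  elements <- ifelse(names(states) %in% distal,
                     "Chromatin interactive region", "n/a")
  elements[names(states) == "rs6903949"] <-
    "TF binding region; chromatin interactive region"
  data.frame(snp_id = names(states),
             is_regulatory = TRUE,
             is_distal = names(states) %in% distal,
             chromatin_states = unname(states),
             regulatory_elements = unname(elements),
             row.names = NULL)
}

# Distal target-gene links; gene_symbol "" when no symbol is annotated
# (the evidence of distal regulation stands regardless).
.gene_link_table <- function() {
  txt <- "
rs9494257 BCLAF1 ENSG00000029363
rs9494257 AHI1 ENSG00000135541
rs9494257 LINC00271 ENSG00000231028
rs6903949 MYB ENSG00000118513
rs6903949 BCLAF1 ENSG00000029363
rs6903949 AHI1 ENSG00000135541
rs6903949 LINC00271 ENSG00000231028
rs6996881 ZNF703 ENSG00000183779
rs6996881 ERLIN2 ENSG00000147475
rs6996881 . ENSG00000183154
rs6996881 . ENSG00000253161
rs4739519 ZNF703 ENSG00000183779
rs4739519 . ENSG00000254290
rs6988263 ZNF703 ENSG00000183779
rs6988263 . ENSG00000254290
rs12156293 ZNF703 ENSG00000183779
rs12156293 . ENSG00000254290
rs12156293 ERLIN2 ENSG00000147475
rs12156293 . ENSG00000183154
rs1568658 . ENSG00000228421
rs1568658 TRIL ENSG00000176734
rs1568658 . ENSG00000255690
rs5994449 DEPDC5 ENSG00000100150
rs5994449 FBXO7 ENSG00000100225
rs5994449 SYN3 ENSG00000185666
rs5994449 PRR14L ENSG00000183530
rs5994449 PISD ENSG00000241878
rs5994449 EIF4ENIF1 ENSG00000184708
rs5994449 RNU6-28 ENSG00000199248
rs5994449 SFI1 ENSG00000198089
rs5753816 YWHAH ENSG00000128245
rs5753816 C22orf24 ENSG00000128254
rs5753816 PISD ENSG00000241878
rs5753816 DEPDC5 ENSG00000100150
rs5753816 RNU6-28 ENSG00000199248
rs5753816 SFI1 ENSG00000198089
rs5753816 EIF4ENIF1 ENSG00000184708
rs5753816 RFPL3S ENSG00000205853
rs5753816 . ENSG00000230736
rs5753816 . ENSG00000243519
rs5753816 . ENSG00000241954
rs5753816 . ENSG00000232218
rs5753816 SYN3 ENSG00000185666"
  df <- utils::read.table(text = txt, header = FALSE,
                          col.names = c("snp_id", "gene_symbol", "ensembl_id"),
                          colClasses = "character")
  df$gene_symbol[df$gene_symbol == "."] <- ""
  df$regulation_type <- "distal transcriptional regulation"
  df
}

#' Regulatory-annotation fixture
#'
#' The packaged regulatory-variant annotations for the 14 enhancer SNPs with
#' regulatory evidence, plus the distal target-gene links for the 9 SNPs
#' involved in distal transcriptional regulation.
#'
#' @return A list with two data.frames: `annotations` (`snp_id`,
#'   `is_regulatory`, `is_distal`, `chromatin_states`,
#'   `regulatory_elements`) and `gene_links` (`snp_id`, `gene_symbol`,
#'   `ensembl_id`, `regulation_type`). Multi-valued annotation cells use
#'   `"; "` as separator; an empty `gene_symbol` means the Ensembl gene has
#'   no annotated symbol.
#' @export
make_annotation_fixture <- function() {
  list(annotations = .annotation_table(), gene_links = .gene_link_table())
}

#' Write the packaged fixture tables to TSV files
#'
#' Materializes the catalog, SNP-locus and annotation fixtures in the exact
#' on-disk dialects the loaders expect, so a pipeline run can be driven
#' entirely from files.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written
#'   (`catalog`, `snps`, `annotations`, `gene_links`).
#' @export
write_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "gwas_catalog.tsv"),
             snps = file.path(dir, "enhancer_snps.bed"),
             annotations = file.path(dir, "annotations.tsv"),
             gene_links = file.path(dir, "gene_links.tsv"))
  write_catalog(make_gwas_fixture(), paths[["catalog"]])
  write_snp_bed(make_snp_fixture(), paths[["snps"]])
  fix <- make_annotation_fixture()
  write_annotations(fix$annotations, fix$gene_links,
                    paths[["annotations"]], paths[["gene_links"]])
  invisible(paths)
}
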