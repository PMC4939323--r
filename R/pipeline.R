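# End-to-end orchestration: gwas-filter -> ld-expand -> call-enhancers ->
# map-snps -> annotate, with every intermediate written to the output
# directory and a manifest recording parameters, input checksums and
# per-stage row counts.

#' Pipeline configuration
#'
#' Paths may be `NULL` where a stage is not wanted: without `catalog`/`ld`
#' the candidate set is taken directly from `snp_bed`; without
#' `annotations` the validation stage is skipped. Parameter defaults are
#' the pipeline's standard operating point: lead p-value cutoff 1e-5,
#' strong-LD cutoff r2 > 0.8, and enhancer log2-ratio cutoff 1.2.
#'
#' @param catalog GWAS catalog TSV (see [load_catalog()]).
#' @param ld Pairwise LD TSV (see [load_ld_table()]).
#' @param me1_reads,me3_reads H3K4me1/H3K4me3 alignments (BAM or read
#'   TSV).
#' @param chrom_sizes Two-column chromosome-sizes file (chrom, length; no
#'   header).
#' @param snp_bed Optional BED6(+1) of SNP loci; supplies coordinates for
#'   candidate members (e.g. leads) and, when no LD expansion is
#'   configured, the candidate set itself.
#' @param annotations,gene_links Annotation tables (see
#'   [load_annotations()]).
#' @param out_dir Output directory.
#' @param p_max Lead p-value cutoff (strict `<`), default 1e-5.
#' @param r2_min LD r2 cutoff (strict `>`), default 0.8.
#' @param ratio_threshold Enhancer log2-ratio cutoff (strict `>`),
#'   default 1.2.
#' @param pseudocount Ratio pseudocount, default 1.
#' @param bin_width Coverage bin width in bp, default 1.
#' @param min_length Minimum enhancer span in bp, default 1.
#' @param merge_gap Maximum gap merged between ratio runs, default 0.
#' @param normalize Reads-per-million scaling before the ratio, default
#'   `TRUE`.
#' @param populations Optional cohort filter applied with `p_max`.
#' @param match_population Population-matched LD expansion, default
#'   `TRUE`.
#' @param seed Optional seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed governs any upstream simulation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(catalog = NULL, ld = NULL,
                            me1_reads = NULL, me3_reads = NULL,
                            chrom_sizes = NULL, snp_bed = NULL,
                            annotations = NULL, gene_links = NULL,
                            out_dir = tempfile("enhsnp_run_"),
                            p_max = 1e-5, r2_min = 0.8,
                            ratio_threshold = 1.2, pseudocount = 1,
                            bin_width = 1, min_length = 1, merge_gap = 0,
                            normalize = TRUE, populations = NULL,
                            match_population = TRUE, seed = NULL) {
  cfg <- list(catalog = catalog, ld = ld, me1_reads = me1_reads,
              me3_reads = me3_reads, chrom_sizes = chrom_sizes,
              snp_bed = snp_bed, annotations = annotations,
              gene_links = gene_links, out_dir = out_dir,
              p_max = p_max, r2_min = r2_min,
              ratio_threshold = ratio_threshold,
              pseudocount = pseudocount, bin_width = bin_width,
              min_length = min_length, merge_gap = merge_gap,
              normalize = normalize, populations = populations,
              match_population = match_population, seed = seed)
  stopifnot(cfg$p_max > 0, cfg$p_max <= 1, cfg$r2_min >= 0, cfg$r2_min <= 1,
            cfg$pseudocount > 0, cfg$bin_width >= 1, cfg$min_length >= 1,
            cfg$merge_gap >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Keys mirror the arguments of [pipeline_config()]; relative
#' paths are resolved against the config file's directory.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  args <- list()
  path_keys <- c("catalog", "ld", "me1_reads", "me3_reads", "chrom_sizes",
                 "snp_bed", "annotations", "gene_links", "out_dir")
  num_keys <- c("p_max", "r2_min", "ratio_threshold", "pseudocount",
                "bin_width", "min_length", "merge_gap", "seed")
  base <- dirname(normalizePath(path))
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% path_keys) {
      args[[k]] <- if (grepl("^/", v)) v else file.path(base, v)
    } else if (k %in% num_keys) {
      args[[k]] <- as.numeric(v)
    } else if (k %in% c("normalize", "match_population")) {
      args[[k]] <- tolower(v) %in% c("true", "yes", "1", "on")
    } else if (k == "populations") {
      args[[k]] <- trimws(strsplit(v, ",")[[1]])
    } else {
      stop("unknown config key: ", k, call. = FALSE)
    }
  }
  do.call(pipeline_config, args)
}

#' Read a chromosome-sizes file
#' @param path Two-column file (chrom, length), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(as.integer(df$length), normalize_chrom(df$chrom))
}

#' Write a chromosome-sizes file
#' @param chrom_lengths Named integer vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(chrom_lengths, path) {
  utils::write.table(data.frame(names(chrom_lengths),
                                as.integer(chrom_lengths)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[enhsnp] stage %-15s done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full enhancer-SNP pipeline
#'
#' Executes gwas-filter, ld-expand, call-enhancers, map-snps and annotate
#' in order, writing every intermediate artifact under
#' `config$out_dir`. A stage failure aborts the run naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest: a list with `parameters`, `inputs` (md5
#'   checksums), `outputs` (md5 checksums), and `counts` (per-stage row
#'   counts, e.g. `n_leads`, `n_enhancer_snps`, `n_regulatory`,
#'   `n_distal`). Also written as `manifest.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  leads <- NULL
  if (!is.null(config$catalog)) {
    leads <- run_stage("gwas-filter", {
      cat_df <- load_catalog(config$catalog)
      filter_leads(cat_df, config$p_max, config$populations)
    })
    write_catalog(leads, file.path(out, "leads.tsv"))
    counts$n_leads <- nrow(leads)
  }

  candidates <- NULL
  if (!is.null(leads) || !is.null(config$ld)) {
    candidates <- run_stage("ld-expand", {
      if (is.null(config$ld)) stop("no LD table configured")
      if (is.null(leads)) stop("no lead catalog configured")
      expand_ld(leads, load_ld_table(config$ld), config$r2_min,
                config$match_population)
    })
    write_candidates(candidates, file.path(out, "candidates"))
    counts$n_candidates <- nrow(candidates)
  }

  enh_env <- run_stage("call-enhancers", {
    if (is.null(config$me1_reads) || is.null(config$me3_reads) ||
        is.null(config$chrom_sizes)) {
      stop("me1_reads, me3_reads and chrom_sizes are required")
    }
    chrom_lengths <- read_chrom_sizes(config$chrom_sizes)
    cov1 <- compute_coverage(load_reads(config$me1_reads), chrom_lengths,
                             config$bin_width)
    cov3 <- compute_coverage(load_reads(config$me3_reads), chrom_lengths,
                             config$bin_width)
    ratios <- lapply(names(chrom_lengths), function(chr) {
      ratio_track(cov1[[chr]], cov3[[chr]], config$pseudocount,
                  config$normalize)
    })
    names(ratios) <- names(chrom_lengths)
    regions <- call_enhancers(ratios, config$ratio_threshold,
                              config$min_length, config$merge_gap)
    list(chrom_lengths = chrom_lengths, ratios = ratios, regions = regions)
  })
  write_regions_bed(enh_env$regions, file.path(out, "enhancers.bed"))
  write_bedgraph(enh_env$ratios, file.path(out, "ratio.bedGraph"))
  counts$n_regions <- nrow(enh_env$regions)

  enhancer_snps <- run_stage("map-snps", {
    loci <- if (!is.null(config$snp_bed)) load_snp_bed(config$snp_bed)
            else NULL
    snps <- candidate_loci(candidates, loci)
    known <- snps$chrom %in% names(enh_env$chrom_lengths)
    if (any(!known)) {
      skipped <- snps[!known, , drop = FALSE]
      write_tsv(skipped, file.path(out, "skipped_snps.tsv"))
      message(sprintf("[enhsnp] %d SNP(s) on chromosomes absent from the coverage data; see skipped_snps.tsv",
                      nrow(skipped)))
      snps <- snps[known, , drop = FALSE]
    }
    intersect_snps(snps, enh_env$regions, enh_env$ratios)
  })
  write_enhancer_snps(enhancer_snps, file.path(out, "enhancer_snps.tsv"))
  counts$n_enhancer_snps <- nrow(enhancer_snps)

  if (!is.null(config$annotations)) {
    summary <- run_stage("annotate", {
      ann <- load_annotations(config$annotations, config$gene_links)
      s <- validate_snps(enhancer_snps, ann)
      write_validation_report(s, ann, file.path(out, "report"))
      s
    })
    counts$n_regulatory <- summary$n_regulatory
    counts$n_distal <- summary$n_distal
  }

  inputs <- unlist(config[c("catalog", "ld", "me1_reads", "me3_reads",
                            "chrom_sizes", "snp_bed", "annotations",
                            "gene_links")])
  out_files <- sort(setdiff(list.files(out, full.names = TRUE),
                            file.path(out, "manifest.txt")))
  manifest <- list(
    parameters = config[c("p_max", "r2_min", "ratio_threshold",
                          "pseudocount", "bin_width", "min_length",
                          "merge_gap", "normalize", "match_population",
                          "seed")],
    inputs = tools::md5sum(inputs),
    outputs = tools::md5sum(out_files),
    counts = counts)
  write_manifest(manifest, file.path(out, "manifest.txt"))
  manifest
}

# Merge the LD candidate set with explicit loci: loci override/fill
# coordinates by snp_id; without a candidate set the loci are the set.
candidate_loci <- function(candidates, loci) {
  if (is.null(candidates)) {
    if (is.null(loci)) stop("no SNP loci configured")
    return(loci)
  }
  snps <- data.frame(snp_id = candidates$member_id,
                     chrom = candidates$chrom,
                     pos0 = candidates$pos0,
                     strand = ".",
                     population = candidates$population)
  if (!is.null(loci)) {
    idx <- match(snps$snp_id, loci$snp_id)
    hit <- !is.na(idx)
    snps$chrom[hit] <- loci$chrom[idx[hit]]
    snps$pos0[hit] <- loci$pos0[idx[hit]]
    snps$strand[hit] <- loci$strand[idx[hit]]
  }
  snps[!is.na(snps$pos0) & !is.na(snps$chrom), , drop = FALSE]
}

write_manifest <- function(manifest, path) {
  fmt <- function(x) {
    if (is.null(x)) "NULL" else paste(format(x, trim = TRUE), collapse = ",")
  }
  lines <- c(
    paste0("parameter.", names(manifest$parameters), " = ",
           vapply(manifest$parameters, fmt, character(1))),
    paste0("input.", basename(names(manifest$inputs)), " = ",
           unname(manifest$inputs)),
    paste0("output.", basename(names(manifest$outputs)), " = ",
           unname(manifest$outputs)),
    paste0("count.", names(manifest$counts), " = ",
           vapply(manifest$counts, fmt, character(1))))
  writeLines(lines, path)
  invisible(path)
}
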