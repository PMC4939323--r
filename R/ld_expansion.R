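# LD expansion stage: widen the lead-SNP set to all proxies in strong
# pairwise linkage disequilibrium (r2 above threshold) with a lead.

#' Load a pairwise LD table
#'
#' Reads tab-separated pairwise LD records with columns `lead_id`,
#' `proxy_id`, `r2`, `population`, `proxy_chrom`, `proxy_pos0` (0-based
#' proxy position). Rows with `r2` outside `[0, 1]` or with
#' `lead_id == proxy_id` are rejected.
#'
#' @param path Path to the LD TSV.
#' @return A data.frame of LD records.
#' @export
load_ld_table <- function(path) {
  df <- read_strict_tsv(path, c("lead_id", "proxy_id", "r2", "population",
                                "proxy_chrom", "proxy_pos0"), "LD")
  df <- df[, c("lead_id", "proxy_id", "r2", "population",
               "proxy_chrom", "proxy_pos0")]
  df$r2 <- parse_numeric_column(df$r2, "r2", path)
  df$proxy_pos0 <- as.integer(parse_numeric_column(df$proxy_pos0,
                                                   "proxy_pos0", path))
  bad <- which(df$r2 < 0 | df$r2 > 1)
  if (length(bad) > 0) {
    stop(sprintf("r2 outside [0, 1] at data row(s) %s of %s",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  self <- which(df$lead_id == df$proxy_id)
  if (length(self) > 0) {
    stop(sprintf("self-pair (lead_id == proxy_id) at data row(s) %s of %s",
                 paste(self, collapse = ", "), path), call. = FALSE)
  }
  df$proxy_chrom <- normalize_chrom(df$proxy_chrom)
  rownames(df) <- NULL
  df
}

#' Write an LD table to TSV
#' @param ld LD data.frame as returned by [load_ld_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ld_table <- function(ld, path) write_tsv(ld, path)

#' Expand lead SNPs through pairwise LD
#'
#' Builds the candidate set: every lead plus every proxy linked to a lead
#' by an LD record with `r2` strictly above `r2_threshold`. Expansion is
#' one hop only (lead to proxy, no transitive closure), and by default
#' population-matched: a lead's proxies are taken only from LD records of
#' the lead's own cohort. A proxy reachable from several leads is kept
#' once, with the maximum-r2 provenance. Leads are always retained, with
#' `NA` coordinates unless they also occur as a proxy of another lead.
#'
#' @param leads Catalog data.frame of lead SNPs (see [load_catalog()]).
#' @param ld LD data.frame (see [load_ld_table()]).
#' @param r2_threshold Keep proxies with `r2` strictly above this
#'   (default 0.8, the conventional strong-LD cutoff).
#' @param match_population When `TRUE` (default) a proxy record only
#'   counts for leads of the same population; `FALSE` pools all records.
#' @return A data.frame with columns `member_id`, `chrom`, `pos0`,
#'   `lead_id`, `r2`, `population`, `is_lead`. For lead rows `lead_id` is
#'   the lead itself and `r2` is `NA`.
#' @export
expand_ld <- function(leads, ld, r2_threshold = 0.8,
                      match_population = TRUE) {
  stopifnot(is.numeric(r2_threshold), length(r2_threshold) == 1,
            r2_threshold >= 0, r2_threshold <= 1)
  lead_rows <- data.frame(member_id = leads$snp_id,
                          chrom = NA_character_,
                          pos0 = NA_integer_,
                          lead_id = leads$snp_id,
                          r2 = NA_real_,
                          population = leads$population,
                          is_lead = rep(TRUE, nrow(leads)))
  if (match_population) {
    key <- paste(ld$lead_id, ld$population)
    lead_key <- paste(leads$snp_id, leads$population)
    hit <- ld[key %in% lead_key & ld$r2 > r2_threshold, , drop = FALSE]
  } else {
    hit <- ld[ld$lead_id %in% leads$snp_id & ld$r2 > r2_threshold, ,
              drop = FALSE]
  }
  proxy_rows <- data.frame(member_id = hit$proxy_id,
                           chrom = hit$proxy_chrom,
                           pos0 = hit$proxy_pos0,
                           lead_id = hit$lead_id,
                           r2 = hit$r2,
                           population = hit$population,
                           is_lead = rep(FALSE, nrow(hit)))
  # keep the best-r2 provenance per proxy id
  if (nrow(proxy_rows) > 0) {
    proxy_rows <- proxy_rows[order(proxy_rows$member_id, -proxy_rows$r2), ,
                             drop = FALSE]
    proxy_rows <- proxy_rows[!duplicated(proxy_rows$member_id), ,
                             drop = FALSE]
    # a SNP that is itself a lead stays a lead
    proxy_rows <- proxy_rows[!(proxy_rows$member_id %in%
                                 lead_rows$member_id), , drop = FALSE]
  }
  lead_rows <- lead_rows[!duplicated(lead_rows$member_id), , drop = FALSE]
  out <- rbind(lead_rows, proxy_rows)
  rownames(out) <- NULL
  out
}

#' Write a candidate set as BED6 plus a provenance TSV
#'
#' Members with known coordinates are written as single-base BED6 records
#' (score 0, strand `.`); the full membership, including leads without
#' coordinates, goes to `<prefix>_provenance.tsv`.
#'
#' @param candidates Candidate-set data.frame from [expand_ld()].
#' @param prefix Output path prefix.
#' @return Invisibly, a named vector with the `bed` and `provenance`
#'   paths.
#' @export
write_candidates <- function(candidates, prefix) {
  bed_path <- paste0(prefix, "_candidates.bed")
  prov_path <- paste0(prefix, "_provenance.tsv")
  placed <- candidates[!is.na(candidates$pos0) & !is.na(candidates$chrom), ,
                       drop = FALSE]
  bed <- data.frame(chrom = placed$chrom,
                    start0 = placed$pos0,
                    end0 = placed$pos0 + 1L,
                    name = placed$member_id,
                    score = 0L,
                    strand = ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(candidates, prov_path)
  invisible(c(bed = bed_path, provenance = prov_path))
}
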