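# Independent brute-force oracles used by the equivalence tests. These
# deliberately avoid the Rle/IRanges code paths of the package.

# Per-base depth by scanning every read against every position.
oracle_depths <- function(reads, chrom, chrom_length) {
  depth <- integer(chrom_length)
  sub <- reads[reads$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    s <- max(sub$start0[i], 0L)
    e <- min(sub$end0[i], chrom_length)
    if (e > s) {
      idx <- (s + 1L):e
      depth[idx] <- depth[idx] + 1L
    }
  }
  depth
}

# Run calling on a plain numeric vector by positional scanning.
oracle_call_runs <- function(values, threshold, min_length, merge_gap) {
  above <- values > threshold
  n <- length(above)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0) {
    return(data.frame(start0 = integer(0), end0 = integer(0)))
  }
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if (r[1] - prev[2] - 1L <= merge_gap) {
      merged[[length(merged)]] <- c(prev[1], r[2])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  out <- do.call(rbind, merged)
  out <- data.frame(start0 = out[, 1] - 1L, end0 = out[, 2])
  out[out$end0 - out$start0 >= min_length, , drop = FALSE]
}

# Containment by exhaustive pairwise check.
oracle_intersect <- function(snps, regions) {
  hits <- character(0)
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(regions))) {
      if (snps$chrom[i] == regions$chrom[j] &&
          snps$pos0[i] >= regions$start0[j] &&
          snps$pos0[i] < regions$end0[j]) {
        hits <- c(hits, snps$snp_id[i])
      }
    }
  }
  sort(unique(hits))
}

# LD expansion by set comprehension over all records.
oracle_expand <- function(leads, ld, r2_threshold) {
  members <- unique(leads$snp_id)
  for (k in seq_len(nrow(ld))) {
    lead_ok <- any(leads$snp_id == ld$lead_id[k] &
                     leads$population == ld$population[k])
    if (lead_ok && ld$r2[k] > r2_threshold) {
      members <- union(members, ld$proxy_id[k])
    }
  }
  sort(members)
}

# A ratio track built directly from a numeric vector (bin width 1).
make_ratio <- function(values, chrom = "chr1") {
  enhsnp:::new_ratio_track(chrom, length(values), 1L,
                           S4Vectors::Rle(values), 1)
}

# Small read set on one chromosome, fixed seed.
random_reads <- function(n, chrom_length, read_length = 10, chrom = "chr1") {
  start0 <- sample.int(chrom_length - read_length, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start0 = start0,
             end0 = start0 + as.integer(read_length))
}
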