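# Independent oracles and fixture builders used across the suite.

# Exact two-sided rank-sum p-value by full enumeration of all size-nx
# subsets of the pooled ranks (midranks for ties). Independent of the
# package's dynamic-programming implementation.
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  r2 <- round(2 * rank(c(x, y)))
  idx <- utils::combn(n, length(x))
  ws <- colSums(matrix(r2[idx], nrow = length(x)))
  w <- sum(r2[seq_along(x)])
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Per-basepair brute-force scan for CNV burden and gene overlap fractions.
# Only usable on small genomes.
oracle_altered_bp <- function(segments, sample_id, neutral_cn = 2L) {
  seg <- segments[segments$sample_id == sample_id, ]
  total <- 0L
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    gmax <- max(s$end)
    cov <- logical(gmax)
    for (i in seq_len(nrow(s))) {
      if (s$total_copy_number[i] != neutral_cn) {
        cov[s$start[i]:s$end[i]] <- TRUE
      }
    }
    total <- total + sum(cov)
  }
  total
}

oracle_gene_overlap <- function(segments, gene, sample_id,
                                direction = c("amp", "del"),
                                amp_cn = 3L, del_cn = 1L) {
  direction <- match.arg(direction)
  seg <- segments[segments$sample_id == sample_id &
                    sub("^chr", "", segments$chrom) ==
                      sub("^chr", "", gene$chrom), ]
  sel <- if (direction == "amp") seg$total_copy_number >= amp_cn
         else seg$total_copy_number <= del_cn
  seg <- seg[sel, , drop = FALSE]
  bp <- gene$start:gene$end
  covered <- rep(FALSE, length(bp))
  for (i in seq_len(nrow(seg))) {
    covered <- covered | (bp >= seg$start[i] & bp <= seg$end[i])
  }
  sum(covered) / length(bp)
}

# Random non-overlapping segment table on a small genome (for oracle tests).
random_small_segments <- function(genome_size, max_segments, sample_id = "s1") {
  n_try <- sample.int(max_segments, 1L)
  cuts <- sort(sample.int(genome_size - 1L, min(n_try, genome_size - 1L)))
  bounds <- unique(c(0L, cuts, genome_size))
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  keep <- sort(sample(seq_along(starts),
                      max(1L, rbinom(1L, length(starts), 0.7))))
  data.frame(
    sample_id = sample_id, chrom = "1",
    start = starts[keep], end = ends[keep],
    total_copy_number = sample(0:5, length(keep), replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Random clone_clusters object for merge-procedure tests.
random_clone_clusters <- function(k = NULL, min_size = 2L, max_size = 12L) {
  if (is.null(k)) k <- sample(2:5, 1L)
  sizes <- sample(min_size:max_size, k, replace = TRUE)
  centers <- runif(k, 0.05, 0.95)
  cp <- unlist(mapply(function(c0, n) pmin(pmax(rnorm(n, c0, 0.05), 0.001), 1),
                      centers, sizes, SIMPLIFY = FALSE))
  vaf <- pmin(pmax(cp / 2 + rnorm(length(cp), 0, 0.02), 0.001), 1)
  clone_clusters(cp = cp, vaf = vaf,
                 cluster = rep(as.character(seq_len(k)), sizes))
}

# Minimal well-formed MAF-like file content for I/O tests.
write_tiny_variant_file <- function(path, rows) {
  header <- paste("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
                  "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification", "distance_to_splice_site",
                  "caller_evidence", "t_depth", "t_alt_count", sep = "\t")
  writeLines(c(header, rows), path)
  path
}
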