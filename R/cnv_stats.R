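# Copy-number burden and gene-level amplification/deletion calls.

#' Copy-number burden
#'
#' CNV burden is the fraction of the genome covered by copy-number-altered
#' segments: the summed span (end - start + 1) of segments whose total copy
#' number differs from `neutral_copy_number` (or whose `is_altered` flag is
#' set), divided by `genome_size_bp`. Segments must be non-overlapping per
#' sample and chromosome, so the sum needs no union step; splitting a
#' segment into adjacent pieces with the same copy number leaves the burden
#' unchanged.
#'
#' @param segments Segment data frame (see [read_segments()]).
#' @param genome_size_bp Total genome size in bp (> 0). The package default
#'   elsewhere is the GRCh37 autosomal total, `clonith_defaults()$genome_size_bp`.
#' @param neutral_copy_number Copy number considered unaltered (default 2;
#'   set differently for sex chromosomes or ploidy-adjusted analyses).
#' @return Data frame with columns `sample_id`, `altered_bp`,
#'   `genome_size_bp`, `burden` (one row per sample).
#' @examples
#' seg <- simulate_segments(genome_size_bp = 1e8, altered_fraction = 0.3,
#'                          n_segments = 10, seed = 1)
#' cnv_burden(seg, genome_size_bp = 1e8)$burden  # 0.3
#' @export
cnv_burden <- function(segments, genome_size_bp,
                       neutral_copy_number = 2L) {
  if (missing(genome_size_bp) || !is.numeric(genome_size_bp) ||
      genome_size_bp <= 0) {
    stop("genome_size_bp must be a positive number")
  }
  validate_segments(segments)
  altered <- if ("is_altered" %in% names(segments)) {
    segments$is_altered | segments$total_copy_number != neutral_copy_number
  } else {
    segments$total_copy_number != neutral_copy_number
  }
  samples <- unique(segments$sample_id)
  altered_bp <- vapply(samples, function(s) {
    sel <- altered & segments$sample_id == s
    sum(segments$end[sel] - segments$start[sel] + 1)
  }, numeric(1L))
  if (any(altered_bp > genome_size_bp)) {
    stop("altered span exceeds genome size for sample(s): ",
         paste(samples[altered_bp > genome_size_bp], collapse = ", "))
  }
  burden <- pmin(pmax(altered_bp / genome_size_bp, 0), 1)
  data.frame(
    sample_id = samples,
    altered_bp = altered_bp,
    genome_size_bp = genome_size_bp,
    burden = burden,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Gene-level amplification/deletion calls by fractional overlap
#'
#' For each gene and sample, computes the fraction of the gene's span
#' covered by the union of amplified segments (total copy number
#' `>= amp_threshold`) and by the union of deleted segments
#' (`<= del_threshold`). A gene is called `amplified` or `deleted` when the
#' corresponding fraction reaches `min_overlap` (default 0.8); when both
#' directions reach the threshold the larger overlap wins, and an exact tie
#' yields `none` with a warning. Overlap is computed on the union of
#' same-direction segments, not per segment, so adjacent same-state
#' segments behave as one.
#'
#' @param segments Segment data frame (see [read_segments()]).
#' @param genes Gene intervals data frame (`gene_id`, `chrom`, `start`,
#'   `end`; 1-based inclusive, see [read_gene_intervals()]).
#' @param amp_threshold Copy number at or above which a segment counts as
#'   amplified (default 3).
#' @param del_threshold Copy number at or below which a segment counts as
#'   deleted (default 1).
#' @param min_overlap Minimum covered gene fraction for a call (default 0.8).
#' @param strip_chr Strip a `"chr"` prefix before comparing chromosome
#'   names (default `TRUE`).
#' @return Data frame with columns `gene_id`, `sample_id`, `call`
#'   (`amplified`/`deleted`/`none`), `overlap_fraction` (winning direction,
#'   or the larger of the two for `none` calls).
#' @export
annotate_gene_cnv <- function(segments, genes,
                              amp_threshold = 3L, del_threshold = 1L,
                              min_overlap = 0.8, strip_chr = TRUE) {
  if (any(genes$end < genes$start) ||
      any(genes$end - genes$start + 1 <= 0)) {
    stop("gene with non-positive length")
  }
  validate_segments(segments)
  gchrom <- normalize_chrom(genes$chrom, strip_chr)
  schrom <- normalize_chrom(segments$chrom, strip_chr)
  samples <- unique(segments$sample_id)
  res <- vector("list", length(samples) * nrow(genes))
  k <- 0L
  for (s in samples) {
    in_s <- segments$sample_id == s
    amp <- in_s & segments$total_copy_number >= amp_threshold
    del <- in_s & segments$total_copy_number <= del_threshold
    for (g in seq_len(nrow(genes))) {
      gene_ir <- IRanges::IRanges(start = genes$start[g], end = genes$end[g])
      gene_len <- genes$end[g] - genes$start[g] + 1
      covered <- function(sel) {
        sel <- sel & schrom == gchrom[g]
        if (!any(sel)) return(0)
        u <- IRanges::reduce(IRanges::IRanges(start = segments$start[sel],
                                              end = segments$end[sel]))
        sum(IRanges::width(IRanges::intersect(u, gene_ir)))
      }
      frac_amp <- covered(amp) / gene_len
      frac_del <- covered(del) / gene_len
      call <- "none"
      frac <- max(frac_amp, frac_del)
      if (frac_amp >= min_overlap || frac_del >= min_overlap) {
        if (frac_amp == frac_del) {
          warning("gene ", genes$gene_id[g], " sample ", s,
                  ": amplified and deleted overlaps tie; call set to none")
        } else {
          call <- if (frac_amp > frac_del) "amplified" else "deleted"
          frac <- max(frac_amp, frac_del)
        }
      }
      k <- k + 1L
      res[[k]] <- data.frame(gene_id = genes$gene_id[g], sample_id = s,
                             call = call, overlap_fraction = frac,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), sample_id = character(0),
                      call = character(0), overlap_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
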