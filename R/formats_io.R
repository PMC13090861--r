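# Tabular I/O: MAF-like variant tables, SEG-like segment tables, loci tables
# from clonal inference, gene intervals, cohort metadata.
#
# Conventions: tab-separated UTF-8, one header line, "#"-prefixed comment
# lines; coordinates 1-based and inclusive on both ends (MAF/SEG style).
# Half-open dialects (BED) are converted at the read boundary.

# Read a TSV keeping track of original file line numbers, so row-level
# validation errors can point at the offending line even with interspersed
# comments.
read_tsv_tracked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  kept <- which(keep)
  if (length(kept) == 0L) stop("no header line in ", path, call. = FALSE)
  df <- utils::read.delim(
    text = paste(lines[kept], collapse = "\n"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character"
  )
  attr(df, "line_numbers") <- kept[-1L]
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Strip an optional "chr" prefix so hg19-style and plain names compare equal.
#' Normalize chromosome names
#'
#' Chromosome labels are stored as given; comparisons strip an optional
#' `"chr"` prefix so `"chr17"` and `"17"` match.
#'
#' @param chrom Character vector of chromosome names.
#' @param strip_chr Strip a leading `"chr"`? Default `TRUE`.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, strip_chr = TRUE) {
  chrom <- as.character(chrom)
  if (strip_chr) sub("^chr", "", chrom) else chrom
}

parse_caller_evidence <- function(x) {
  # "mutect:KEEP;strelka:PASS" -> named character vector
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(pairs) {
    pairs <- pairs[nzchar(pairs)]
    if (length(pairs) == 0L) return(stats::setNames(character(0), character(0)))
    parts <- strsplit(pairs, ":", fixed = TRUE)
    flags <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
    stats::setNames(flags, vapply(parts, `[[`, "", 1L))
  })
}

format_caller_evidence <- function(ev) {
  vapply(ev, function(e) paste(names(e), e, sep = ":", collapse = ";"), "")
}

#' Read a MAF-like somatic variant table
#'
#' Reads a tab-separated variant table with MAF-style columns
#' (`Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`,
#' `t_depth`, `t_alt_count`, `caller_evidence`; optionally `Hugo_Symbol` and
#' `distance_to_splice_site`) into the internal variant representation used
#' by [filter_variants()] and [compute_tmb()]. `caller_evidence` holds
#' `caller:flag` pairs separated by `";"`, e.g. `"mutect:KEEP;strelka:PASS"`.
#'
#' Row-level validation enforces `t_alt_count <= t_depth`, positive depth,
#' and (when a `vaf` column is present) consistency of `vaf` with
#' `t_alt_count / t_depth` to within 1e-4. Invalid rows are reported with
#' their file line numbers.
#'
#' @param path Path to the TSV file.
#' @param dialect Input dialect; only `"maf_like"` is defined.
#' @param on_invalid `"error"` (default) aborts listing offending lines;
#'   `"drop"` removes invalid rows and attaches them as the `"rejected"`
#'   attribute (`line`, `reason`), so no row is silently lost.
#' @return A data frame of variant records with columns `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `variant_classification`, `effect_class`,
#'   `distance_to_splice_site`, `caller_evidence`, `depth`, `alt_count`,
#'   `vaf`.
#' @seealso [write_variant_table()], [classify_effect()]
#' @export
read_variant_table <- function(path, dialect = c("maf_like"),
                               on_invalid = c("error", "drop")) {
  dialect <- match.arg(dialect)
  on_invalid <- match.arg(on_invalid)
  raw <- read_tsv_tracked(path)
  lines <- attr(raw, "line_numbers")
  require_columns(raw, c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                         "Reference_Allele", "Tumor_Seq_Allele2",
                         "Variant_Classification", "t_depth", "t_alt_count",
                         "caller_evidence"),
                  "variant table")
  n <- nrow(raw)
  out <- data.frame(
    sample_id = as.character(raw$Tumor_Sample_Barcode),
    chrom = as.character(raw$Chromosome),
    pos = num_or_na(raw$Start_Position),
    ref = as.character(raw$Reference_Allele),
    alt = as.character(raw$Tumor_Seq_Allele2),
    gene = if ("Hugo_Symbol" %in% names(raw)) as.character(raw$Hugo_Symbol) else NA_character_,
    variant_classification = as.character(raw$Variant_Classification),
    distance_to_splice_site = if ("distance_to_splice_site" %in% names(raw))
      num_or_na(raw$distance_to_splice_site) else NA_real_,
    caller_evidence = as.character(raw$caller_evidence),
    depth = num_or_na(raw$t_depth),
    alt_count = num_or_na(raw$t_alt_count),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, n)
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(out$pos) | is.na(out$depth) | is.na(out$alt_count),
                "unparseable numeric field")
  reason <- bad(!is.na(out$depth) & out$depth <= 0, "non-positive depth")
  reason <- bad(!is.na(out$alt_count) & (out$alt_count < 0 | out$alt_count > out$depth),
                "alt_count > depth")
  ev <- parse_caller_evidence(out$caller_evidence)
  reason <- bad(lengths(ev) == 0L, "empty caller_evidence")
  out$vaf <- out$alt_count / out$depth
  if ("vaf" %in% names(raw)) {
    given <- num_or_na(raw$vaf)
    reason <- bad(!is.na(given) & abs(given - out$vaf) > 1e-4,
                  "vaf inconsistent with alt_count/depth")
  }
  invalid <- !is.na(reason)
  if (any(invalid)) {
    msg <- paste0("line ", lines[invalid], ": ", reason[invalid])
    if (on_invalid == "error") {
      stop("invalid variant row(s):\n  ", paste(msg, collapse = "\n  "),
           call. = FALSE)
    }
    message(sum(invalid), " variant row(s) rejected")
  }
  kept <- out[!invalid, , drop = FALSE]
  rownames(kept) <- NULL
  kept$effect_class <- classify_effect(kept$variant_classification,
                                       kept$distance_to_splice_site)
  if (any(invalid)) {
    attr(kept, "rejected") <- data.frame(line = lines[invalid],
                                         reason = reason[invalid],
                                         stringsAsFactors = FALSE)
  }
  kept
}

#' Write a MAF-like variant table
#'
#' Inverse of [read_variant_table()]; a write-then-read round trip
#' reproduces all fields.
#'
#' @param records Variant data frame as returned by [read_variant_table()]
#'   or [simulate_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  out <- data.frame(
    Hugo_Symbol = records$gene,
    Tumor_Sample_Barcode = records$sample_id,
    Chromosome = records$chrom,
    Start_Position = records$pos,
    Reference_Allele = records$ref,
    Tumor_Seq_Allele2 = records$alt,
    Variant_Classification = records$variant_classification,
    distance_to_splice_site = records$distance_to_splice_site,
    caller_evidence = records$caller_evidence,
    t_depth = records$depth,
    t_alt_count = records$alt_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-like copy-number segment table
#'
#' Reads tab-separated segments (`sample`, `chrom`, `start`, `end`,
#' `total_copy_number`; 1-based inclusive coordinates), checks per-sample
#' per-chromosome non-overlap, and returns segments sorted by sample,
#' chromosome and start. `is_altered` is derived as
#' `total_copy_number != neutral_copy_number`.
#'
#' @param path Path to the TSV file.
#' @param neutral_copy_number Copy number considered unaltered (default 2).
#' @return Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `total_copy_number`, `is_altered`.
#' @export
read_segments <- function(path, neutral_copy_number = 2L) {
  raw <- read_tsv_tracked(path)
  require_columns(raw, c("sample", "chrom", "start", "end",
                         "total_copy_number"), "segment table")
  seg <- data.frame(
    sample_id = as.character(raw$sample),
    chrom = as.character(raw$chrom),
    start = num_or_na(raw$start),
    end = num_or_na(raw$end),
    total_copy_number = num_or_na(raw$total_copy_number),
    stringsAsFactors = FALSE
  )
  if (nrow(seg) > 0L) {
    if (anyNA(seg$start) || anyNA(seg$end) || anyNA(seg$total_copy_number))
      stop("segment table: unparseable numeric field", call. = FALSE)
    if (any(seg$start > seg$end))
      stop("segment table: start > end at line(s) ",
           paste(attr(raw, "line_numbers")[seg$start > seg$end], collapse = ", "),
           call. = FALSE)
    seg$total_copy_number <- as.integer(seg$total_copy_number)
    if (any(seg$total_copy_number < 0))
      stop("segment table: negative copy number", call. = FALSE)
    validate_segments(seg)
    seg <- seg[order(seg$sample_id, seg$chrom, seg$start), , drop = FALSE]
    rownames(seg) <- NULL
  } else {
    seg$total_copy_number <- integer(0)
  }
  seg$is_altered <- seg$total_copy_number != neutral_copy_number
  seg
}

# Error if any two segments of the same sample/chromosome overlap; names the
# offending pair. Sorted-scan: after ordering by start, an overlap exists iff
# a segment starts at or before the previous one ends.
validate_segments <- function(seg) {
  if (nrow(seg) < 2L) return(invisible(seg))
  key <- paste(seg$sample_id, normalize_chrom(seg$chrom), sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    idx <- idx[order(seg$start[idx])]
    hit <- which(seg$start[idx][-1L] <= seg$end[idx][-length(idx)])
    if (length(hit) > 0L) {
      a <- idx[hit[1L]]
      b <- idx[hit[1L] + 1L]
      stop(sprintf(
        "overlapping segments for sample %s chrom %s: [%s,%s] and [%s,%s]",
        seg$sample_id[a], seg$chrom[a],
        seg$start[a], seg$end[a], seg$start[b], seg$end[b]), call. = FALSE)
    }
  }
  invisible(seg)
}

#' Write a SEG-like segment table
#'
#' @param segments Segment data frame as returned by [read_segments()] or
#'   [simulate_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    sample = segments$sample_id,
    chrom = segments$chrom,
    start = segments$start,
    end = segments$end,
    total_copy_number = segments$total_copy_number,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clonal-inference loci table
#'
#' Reads the per-mutation output dialect of a clonal-inference tool:
#' `mutation_id`, `sample_id`, `cluster_id`, `cellular_prevalence`, and
#' either `variant_allele_frequency` or the pair `ref_count`/`alt_count`
#' from which VAF is computed as `alt / (ref + alt)`.
#'
#' Cellular prevalences outside `[0, 1]` by at most 1e-6 are clipped with a
#' warning; larger excursions are a validation error. Duplicate
#' `mutation_id` values within a sample are an error.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `mutation_id`, `sample_id`, `cluster_id`,
#'   `cellular_prevalence`, `vaf`, `ref_count`, `alt_count` (count columns
#'   `NA` when absent from the input).
#' @export
read_loci_table <- function(path) {
  raw <- read_tsv_tracked(path)
  require_columns(raw, c("mutation_id", "sample_id", "cellular_prevalence"),
                  "loci table")
  n <- nrow(raw)
  loci <- data.frame(
    mutation_id = as.character(raw$mutation_id),
    sample_id = as.character(raw$sample_id),
    cluster_id = if ("cluster_id" %in% names(raw))
      num_or_na(raw$cluster_id) else NA_real_,
    cellular_prevalence = num_or_na(raw$cellular_prevalence),
    ref_count = if ("ref_count" %in% names(raw))
      num_or_na(raw$ref_count) else NA_real_,
    alt_count = if ("alt_count" %in% names(raw))
      num_or_na(raw$alt_count) else NA_real_,
    stringsAsFactors = FALSE
  )
  if ("variant_allele_frequency" %in% names(raw)) {
    loci$vaf <- num_or_na(raw$variant_allele_frequency)
  } else if (all(c("ref_count", "alt_count") %in% names(raw))) {
    loci$vaf <- loci$alt_count / (loci$ref_count + loci$alt_count)
  } else {
    stop("loci table: need variant_allele_frequency or ref_count/alt_count",
         call. = FALSE)
  }
  if (n > 0L) {
    if (anyNA(loci$cellular_prevalence))
      stop("loci table: unparseable cellular_prevalence", call. = FALSE)
    cp <- loci$cellular_prevalence
    out_of_range <- cp < -1e-6 | cp > 1 + 1e-6
    if (any(out_of_range)) {
      stop("loci table: cellular_prevalence outside [0,1] at line(s) ",
           paste(attr(raw, "line_numbers")[out_of_range], collapse = ", "),
           call. = FALSE)
    }
    if (any(cp < 0 | cp > 1)) {
      warning("cellular_prevalence value(s) clipped to [0,1] (|excess| <= 1e-6)")
      loci$cellular_prevalence <- pmin(pmax(cp, 0), 1)
    }
    dup <- duplicated(loci[, c("sample_id", "mutation_id")])
    if (any(dup)) {
      stop("loci table: duplicate mutation_id within sample: ",
           paste(unique(loci$mutation_id[dup]), collapse = ", "), call. = FALSE)
    }
  }
  loci
}

#' Write a clonal-inference loci table
#'
#' @param loci Loci data frame as returned by [read_loci_table()] or
#'   [simulate_subclonal_tumor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_table <- function(loci, path) {
  out <- data.frame(
    mutation_id = loci$mutation_id,
    sample_id = loci$sample_id,
    cluster_id = loci$cluster_id,
    cellular_prevalence = loci$cellular_prevalence,
    variant_allele_frequency = loci$vaf,
    ref_count = loci$ref_count,
    alt_count = loci$alt_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals
#'
#' Reads gene intervals either as BED (0-based half-open, columns chrom,
#' start, end, name; converted to 1-based inclusive at the boundary) or as a
#' headered TSV already in 1-based inclusive coordinates (`gene_id`,
#' `chrom`, `start`, `end`).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (headered, 1-based inclusive) or `"bed"`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @export
read_gene_intervals <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    genes <- data.frame(
      gene_id = as.character(raw[[4L]]),
      chrom = as.character(raw[[1L]]),
      start = as.numeric(raw[[2L]]) + 1,  # half-open -> 1-based inclusive
      end = as.numeric(raw[[3L]]),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- read_tsv_tracked(path)
    require_columns(raw, c("gene_id", "chrom", "start", "end"), "gene table")
    genes <- data.frame(
      gene_id = as.character(raw$gene_id),
      chrom = as.character(raw$chrom),
      start = num_or_na(raw$start),
      end = num_or_na(raw$end),
      stringsAsFactors = FALSE
    )
  }
  if (any(genes$end < genes$start))
    stop("gene table: end < start", call. = FALSE)
  genes
}

#' Read a cohort metadata/metrics table
#'
#' Reads sample-level metadata (`sample_id`, and optionally `histotype`,
#' `disease_status`, `tumor_location`, `purity`) plus any numeric metric
#' columns (e.g. `ith`, `tmb`, `cnv_burden`). `sample_id` must be unique;
#' `purity`, when present, must lie in (0, 1].
#'
#' @param path Path to the TSV file.
#' @return Data frame, one row per sample.
#' @export
read_cohort_table <- function(path) {
  raw <- read_tsv_tracked(path)
  require_columns(raw, "sample_id", "cohort table")
  if (anyDuplicated(raw$sample_id))
    stop("cohort table: duplicate sample_id", call. = FALSE)
  out <- as.data.frame(raw, stringsAsFactors = FALSE)
  attr(out, "line_numbers") <- NULL
  for (col in setdiff(names(out), c("sample_id", "histotype", "disease_status",
                                    "tumor_location"))) {
    out[[col]] <- num_or_na(raw[[col]])
  }
  if ("purity" %in% names(out)) {
    p <- out$purity
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      stop("cohort table: purity outside (0,1]", call. = FALSE)
  }
  out
}
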