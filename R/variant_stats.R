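# Variant retention filtering and tumor mutational burden.

# MAF-style classes counted as nonsilent (protein-impacting).
NONSILENT_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins",
  "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site", "Splice_Site", "Splice_Region"
)
SILENT_CLASSES <- c("Silent", "Synonymous")
OTHER_KNOWN_CLASSES <- c(
  "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
  "lincRNA", "Nonsense", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"
)

#' Classify variant effect
#'
#' Maps a MAF-style `Variant_Classification` plus an optional distance to
#' the nearest splice site onto the four effect classes used for TMB:
#' a variant within 2 bp of a splice site is `splicing` regardless of its
#' annotated class; otherwise protein-impacting classes (missense, nonsense,
#' frameshift, in-frame indel, translation start/stop, splice-site classes)
#' are `nonsilent`, synonymous classes are `silent`, and everything else is
#' `other`. Unknown classification strings yield `other` with a warning,
#' never an error.
#'
#' @param variant_classification Character vector of MAF-style classes.
#' @param distance_to_splice_site Integer distance in bp, or `NA` when not
#'   annotated; values `<= 2` force the `splicing` class.
#' @return Character vector in `{nonsilent, silent, splicing, other}`.
#' @examples
#' classify_effect("Missense_Mutation", NA)
#' classify_effect("Silent", 2)   # splice proximity wins
#' @export
classify_effect <- function(variant_classification,
                            distance_to_splice_site = NA_real_) {
  vc <- as.character(variant_classification)
  n <- length(vc)
  dss <- rep_len(as.numeric(distance_to_splice_site), n)
  out <- rep("other", n)
  out[vc %in% NONSILENT_CLASSES] <- "nonsilent"
  out[vc %in% SILENT_CLASSES] <- "silent"
  out[!is.na(dss) & dss <= 2] <- "splicing"
  unknown <- !(vc %in% c(NONSILENT_CLASSES, SILENT_CLASSES, OTHER_KNOWN_CLASSES))
  unknown <- unknown & out != "splicing"
  if (any(unknown)) {
    warning("unknown Variant_Classification value(s) treated as 'other': ",
            paste(unique(vc[unknown]), collapse = ", "))
  }
  out
}

#' Filter somatic variants by the retention criteria
#'
#' Retains variants with allele frequency `>= af_min`, read depth
#' `>= depth_min`, evidence from at least `min_callers` callers, and — for
#' every caller named in `required_flags` that appears in a record's
#' evidence — the matching flag (e.g. `KEEP` for MuTect and `PASS` for
#' Strelka). Flags are only enforced for callers present in the record's
#' evidence set. Input order is preserved; rejected records are attached as
#' the `"rejected"` attribute with the first failing criterion (checked in
#' the order `vaf`, `depth`, `callers`, `flag`).
#'
#' Filtering is idempotent: applying it to an already-filtered set changes
#' nothing.
#'
#' @param records Variant data frame (see [read_variant_table()]).
#' @param af_min Minimum variant allele frequency (default 0.05).
#' @param depth_min Minimum read depth (default 10).
#' @param min_callers Minimum number of supporting callers (default 2).
#' @param required_flags Named character vector `caller = flag`.
#' @return The retained records, with attribute `"rejected"` (data frame
#'   `row`, `reason`) when any were removed.
#' @export
filter_variants <- function(records,
                            af_min = 0.05,
                            depth_min = 10L,
                            min_callers = 2L,
                            required_flags = c(mutect = "KEEP",
                                               strelka = "PASS")) {
  n <- nrow(records)
  if (n == 0L) return(records)
  ev <- parse_caller_evidence(records$caller_evidence)
  flag_ok <- vapply(ev, function(e) {
    shared <- intersect(names(e), names(required_flags))
    all(e[shared] == required_flags[shared])
  }, logical(1L))
  reason <- rep(NA_character_, n)
  set_reason <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- set_reason(records$vaf < af_min, "vaf")
  reason <- set_reason(records$depth < depth_min, "depth")
  reason <- set_reason(lengths(ev) < min_callers, "callers")
  reason <- set_reason(!flag_ok, "flag")
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- NULL
  if (any(!keep)) {
    attr(out, "rejected") <- data.frame(row = which(!keep),
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
    message(sum(!keep), " variant(s) removed by retention filter")
  }
  out
}

#' Classify a TMB value
#'
#' Applies the pediatric TMB classes: `hypermutator` for TMB strictly above
#' 10 muts/Mb, `pediatric_high` for TMB between 2 and 10 muts/Mb
#' (inclusive on both ends), `low` otherwise.
#'
#' @param tmb Numeric vector of TMB values (muts/Mb), non-negative.
#' @return Character vector in `{low, pediatric_high, hypermutator}`.
#' @examples
#' classify_tmb(c(0.54, 5, 12))
#' @export
classify_tmb <- function(tmb) {
  if (any(is.na(tmb)) || any(tmb < 0)) stop("tmb must be non-negative")
  ifelse(tmb > 10, "hypermutator",
         ifelse(tmb >= 2, "pediatric_high", "low"))
}

#' Compute tumor mutational burden
#'
#' TMB is the frequency of nonsilent somatic mutations per sequenced
#' megabase: the count of records with effect class `nonsilent` or
#' `splicing` divided by `exome_size_mb`. Records are expected to have
#' passed [filter_variants()] already. One result row is produced per
#' sample present in `records`.
#'
#' @param records Filtered variant data frame.
#' @param exome_size_mb Sequenced exome size in megabases (> 0); required,
#'   with no default (capture design size or per-sample covered footprint,
#'   at the caller's discretion).
#' @param sample_id Optional sample label used when `records` is empty.
#' @return Data frame with columns `sample_id`, `n_nonsilent`,
#'   `exome_size_mb`, `tmb`, `category`.
#' @examples
#' v <- simulate_variant_table(n_nonsilent = 33, n_silent = 5, seed = 1)
#' compute_tmb(v, exome_size_mb = 60)  # tmb = 0.55
#' @export
compute_tmb <- function(records, exome_size_mb, sample_id = NULL) {
  if (missing(exome_size_mb) || is.null(exome_size_mb) ||
      !is.numeric(exome_size_mb) || exome_size_mb <= 0) {
    stop("exome_size_mb must be a positive number (no default)")
  }
  samples <- unique(records$sample_id)
  if (length(samples) == 0L) samples <- if (is.null(sample_id)) character(0) else sample_id
  counted <- records$effect_class %in% c("nonsilent", "splicing")
  n_ns <- vapply(samples,
                 function(s) sum(counted & records$sample_id == s),
                 integer(1L))
  tmb <- n_ns / exome_size_mb
  data.frame(
    sample_id = samples,
    n_nonsilent = as.integer(n_ns),
    exome_size_mb = exome_size_mb,
    tmb = tmb,
    category = if (length(tmb)) classify_tmb(tmb) else character(0),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
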