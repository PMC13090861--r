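# Group-wise comparison of sample-level metrics (ITH, TMB, CNV burden)
# with two-sided rank-sum tests and median summaries.

#' Compare a metric between two cohort groups
#'
#' Two-sided rank-sum comparison of a sample-level metric between two
#' levels of a grouping variable. Ties are handled with midranks; the
#' exact null distribution is enumerated whenever the smaller group has at
#' most `exact_max_n` samples, otherwise the continuity-corrected normal
#' approximation is used. Samples with a missing metric are excluded and
#' counted (attribute `"n_missing"`). No multiple-testing correction is
#' applied here; see [compare_pairs()] for an optional
#' Benjamini-Hochberg adjustment across several contrasts.
#'
#' @param table Cohort data frame (one row per sample).
#' @param metric Name of the numeric metric column.
#' @param group_field Name of the grouping column.
#' @param pair Character vector of length 2: the two group levels to
#'   compare.
#' @param exact_max_n Exact-path threshold (default 10).
#' @return One-row data frame: `metric`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `median_a`, `median_b`, `p_value`, `method`.
#' @examples
#' tbl <- data.frame(sample_id = letters[1:6],
#'                   group = rep(c("x", "y"), each = 3),
#'                   ith = c(1, 2, 3, 4, 5, 6))
#' compare_groups(tbl, "ith", "group", c("x", "y"))$p_value  # 0.1
#' @export
compare_groups <- function(table, metric, group_field, pair,
                           exact_max_n = 10L) {
  stopifnot(length(pair) == 2L)
  if (!metric %in% names(table)) stop("unknown metric column: ", metric)
  if (!group_field %in% names(table)) stop("unknown group column: ", group_field)
  vals <- as.numeric(table[[metric]])
  grp <- as.character(table[[group_field]])
  n_missing <- 0L
  take <- function(level) {
    v <- vals[grp == level]
    n_missing <<- n_missing + sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("group '", level, "' has no usable samples for metric '",
           metric, "'")
    }
    v
  }
  a <- take(pair[1L])
  b <- take(pair[2L])
  ts <- ranksum_test(a, b, exact_max_n = exact_max_n)
  out <- data.frame(
    metric = metric, group_a = pair[1L], group_b = pair[2L],
    n_a = length(a), n_b = length(b),
    median_a = stats::median(a), median_b = stats::median(b),
    p_value = ts$p_value, method = ts$method,
    stringsAsFactors = FALSE
  )
  attr(out, "n_missing") <- n_missing
  out
}

#' Compare a metric across several group pairs
#'
#' Applies [compare_groups()] to each requested pair, optionally adjusting
#' p-values across the pairs with the Benjamini-Hochberg procedure
#' (off by default: raw two-sided rank-sum p-values are reported).
#'
#' @param table,metric,group_field,exact_max_n As in [compare_groups()].
#' @param pairs List of length-2 character vectors.
#' @param bh Apply Benjamini-Hochberg adjustment across the pairs
#'   (default `FALSE`).
#' @return Data frame with one row per pair; an extra `p_adjusted` column
#'   when `bh = TRUE`.
#' @export
compare_pairs <- function(table, metric, group_field, pairs,
                          bh = FALSE, exact_max_n = 10L) {
  res <- do.call(rbind, lapply(pairs, function(p) {
    compare_groups(table, metric, group_field, p, exact_max_n)
  }))
  rownames(res) <- NULL
  if (bh) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Per-group median summaries of a metric
#'
#' One row per observed group level: sample count, median (midpoint
#' convention for even sizes, as in [stats::median()]), minimum and
#' maximum. Samples with a missing metric are excluded; group levels with
#' no usable samples are absent from the output.
#'
#' @param table Cohort data frame.
#' @param metric Name of the numeric metric column.
#' @param group_field Name of the grouping column.
#' @return Data frame with columns `group`, `n`, `median`, `min`, `max`.
#' @export
summarize_medians <- function(table, metric, group_field) {
  if (!metric %in% names(table)) stop("unknown metric column: ", metric)
  if (!group_field %in% names(table)) stop("unknown group column: ", group_field)
  vals <- as.numeric(table[[metric]])
  grp <- as.character(table[[group_field]])
  keep <- !is.na(vals)
  vals <- vals[keep]; grp <- grp[keep]
  levels <- unique(grp)
  out <- do.call(rbind, lapply(levels, function(l) {
    v <- vals[grp == l]
    data.frame(group = l, n = length(v), median = stats::median(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(group = character(0), n = integer(0),
                      median = numeric(0), min = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
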