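# Synthetic tumors, segment tables, variant tables and cohorts with the
# statistical structure the downstream analyses assume. All generators are
# deterministic given their seed (equal seeds give byte-identical output).

#' Simulate a subclonal tumor
#'
#' Generates a loci table for a tumor composed of the given subclones. For
#' each mutation of subclone `j`, read depth is drawn from a Poisson with
#' mean `mean_depth` (truncated at 1); the expected VAF is
#' `purity * CP_j * m / (purity * C + 2 * (1 - purity))` with multiplicity
#' `m = 1` and tumor copy number `C` (default 2); the alt read count is
#' binomial at that expected VAF. The `cellular_prevalence` column holds
#' the per-mutation maximum-likelihood CP implied by the observed VAF (the
#' inverse mapping, clipped to `[0, 1]`) — the same shape an external
#' clonal-inference tool emits — and `cluster_id` holds the true subclone
#' index.
#'
#' @param subclone_cp Vector of subclone cellular prevalences in `(0, 1]`.
#' @param mutations_per_subclone Vector of positive mutation counts, same
#'   length as `subclone_cp`.
#' @param purity Tumor purity in `(0, 1]` (default 1).
#' @param mean_depth Mean sequencing depth (default 500).
#' @param tumor_copy_number Tumor total copy number (default 2).
#' @param seed Integer seed.
#' @param sample_id Sample label (default `"sim1"`).
#' @return List with elements `loci` (data frame `mutation_id`,
#'   `sample_id`, `cluster_id`, `cellular_prevalence`, `vaf`, `ref_count`,
#'   `alt_count`) and `truth` (the generating parameters plus the true
#'   Shannon ITH computed from normalized true CPs).
#' @examples
#' sim <- simulate_subclonal_tumor(c(1, 0.4), c(50, 50), seed = 7)
#' sim$truth$ith_true
#' @export
simulate_subclonal_tumor <- function(subclone_cp, mutations_per_subclone,
                                     purity = 1, mean_depth = 500,
                                     tumor_copy_number = 2L, seed = 1L,
                                     sample_id = "sim1") {
  stopifnot(length(subclone_cp) == length(mutations_per_subclone),
            length(subclone_cp) >= 1L,
            all(mutations_per_subclone >= 1L))
  if (any(subclone_cp <= 0 | subclone_cp > 1)) {
    stop("subclone_cp must lie in (0, 1]")
  }
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  exp_vaf <- cp_to_vaf(subclone_cp, purity, tumor_copy_number)
  if (any(exp_vaf > 1)) stop("expected VAF exceeds 1; check configuration")
  k <- length(subclone_cp)
  n <- sum(mutations_per_subclone)
  cluster_id <- rep(seq_len(k), mutations_per_subclone)
  loci <- withr::with_seed(seed, {
    depth <- pmax(1L, stats::rpois(n, mean_depth))
    alt <- stats::rbinom(n, depth, exp_vaf[cluster_id])
    vaf <- alt / depth
    data.frame(
      mutation_id = sprintf("%s_m%04d", sample_id, seq_len(n)),
      sample_id = sample_id,
      cluster_id = cluster_id,
      cellular_prevalence = vaf_to_cp(vaf, purity, tumor_copy_number),
      vaf = vaf,
      ref_count = depth - alt,
      alt_count = alt,
      stringsAsFactors = FALSE
    )
  })
  p_true <- subclone_cp / sum(subclone_cp)
  ith_true <- if (k == 1L) 0 else -sum(p_true * log(p_true))
  list(
    loci = loci,
    truth = list(subclone_cp = subclone_cp,
                 mutations_per_subclone = mutations_per_subclone,
                 purity = purity, mean_depth = mean_depth,
                 tumor_copy_number = tumor_copy_number, seed = seed,
                 sample_id = sample_id, expected_vaf = exp_vaf,
                 proportions_true = p_true, ith_true = ith_true)
  )
}

#' Simulate a copy-number segment table
#'
#' Generates non-overlapping segments tiling a genome such that the altered
#' segments span exactly `round(altered_fraction * genome_size_bp)` bp.
#' Altered and neutral spans are randomly composed and interleaved;
#' altered segments receive a copy number drawn from `{0, 1, 3, 4, 5}`.
#'
#' @param genome_size_bp Genome size in bp.
#' @param altered_fraction Target fraction of the genome altered, in
#'   `[0, 1]`.
#' @param n_segments Number of segments to generate.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param neutral_copy_number Copy number of unaltered segments (default 2).
#' @return Segment data frame (`sample_id`, `chrom`, `start`, `end`,
#'   `total_copy_number`, `is_altered`), single chromosome `"1"`.
#' @export
simulate_segments <- function(genome_size_bp, altered_fraction, n_segments,
                              seed = 1L, sample_id = "sim1",
                              neutral_copy_number = 2L) {
  if (altered_fraction < 0 || altered_fraction > 1) {
    stop("altered_fraction must lie in [0, 1]")
  }
  target <- round(altered_fraction * genome_size_bp)
  if (target > genome_size_bp) stop("altered span exceeds genome size")
  withr::with_seed(seed, {
    n_alt <- if (target == 0) 0L else max(1L, round(n_segments * altered_fraction))
    n_alt <- min(n_alt, n_segments, target)
    n_neu <- min(n_segments - n_alt, genome_size_bp - target)
    lens_alt <- compose_lengths(target, n_alt)
    lens_neu <- compose_lengths(genome_size_bp - target, n_neu)
    status <- sample(c(rep(TRUE, n_alt), rep(FALSE, n_neu)))
    lens <- numeric(length(status))
    lens[status] <- lens_alt
    lens[!status] <- lens_neu
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    cn <- ifelse(status,
                 sample(setdiff(0:5, neutral_copy_number), length(status),
                        replace = TRUE),
                 neutral_copy_number)
    data.frame(
      sample_id = sample_id,
      chrom = "1",
      start = starts,
      end = ends,
      total_copy_number = as.integer(cn),
      is_altered = status,
      stringsAsFactors = FALSE
    )
  })
}

# Random composition of `total` into `n` positive integer-valued parts.
# Numeric (not integer) arithmetic: genome sizes exceed the integer range.
compose_lengths <- function(total, n) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(as.numeric(total))
  cuts <- sort(sample.int(total - 1, n - 1))
  diff(c(0, cuts, total))
}

VOCAB_NONSILENT_SIM <- c("Missense_Mutation", "Nonsense_Mutation",
                         "Frame_Shift_Del", "Frame_Shift_Ins",
                         "In_Frame_Del", "Splice_Site")

#' Simulate a MAF-like variant table
#'
#' Generates a variant table with the requested numbers of nonsilent and
#' silent mutations, all satisfying the retention filters by construction
#' (VAF >= 0.05, depth >= 10, two-caller evidence with the required
#' flags). `spike_failures` additionally injects known-bad nonsilent rows
#' cycling through the failure modes (depth < 10, VAF < 0.05,
#' single-caller evidence, wrong caller flag) so a downstream filter can be
#' checked against an exact expected removal count.
#'
#' @param n_nonsilent Number of nonsilent (TMB-countable) variants.
#' @param n_silent Number of silent variants.
#' @param exome_size_mb Exome size used to draw positions (default 60).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param spike_failures Number of filter-failing rows to inject
#'   (default 0).
#' @return Variant data frame in the internal representation of
#'   [read_variant_table()].
#' @export
simulate_variant_table <- function(n_nonsilent, n_silent,
                                   exome_size_mb = 60, seed = 1L,
                                   sample_id = "sim1",
                                   spike_failures = 0L) {
  stopifnot(n_nonsilent >= 0L, n_silent >= 0L, spike_failures >= 0L)
  n <- n_nonsilent + n_silent + spike_failures
  withr::with_seed(seed, {
    vc <- c(
      if (n_nonsilent > 0) sample(VOCAB_NONSILENT_SIM, n_nonsilent,
                                  replace = TRUE),
      rep("Silent", n_silent),
      if (spike_failures > 0) sample(VOCAB_NONSILENT_SIM, spike_failures,
                                     replace = TRUE)
    )
    depth <- pmax(10L, stats::rpois(n, 100))
    vaf_target <- stats::runif(n, 0.10, 0.60)
    alt <- pmin(depth, pmax(ceiling(0.05 * depth), round(vaf_target * depth)))
    evidence <- rep("mutect:KEEP;strelka:PASS", n)
    three <- stats::runif(n) < 0.3
    evidence[three] <- "mutect:KEEP;strelka:PASS;varscan2:SS"
    if (spike_failures > 0) {
      idx <- n_nonsilent + n_silent + seq_len(spike_failures)
      mode <- (seq_len(spike_failures) - 1L) %% 4L
      for (i in seq_along(idx)) {
        j <- idx[i]
        if (mode[i] == 0L) {          # shallow depth
          depth[j] <- 9L
          alt[j] <- max(1L, round(0.3 * depth[j]))
        } else if (mode[i] == 1L) {   # sub-threshold VAF
          depth[j] <- 200L
          alt[j] <- 6L                # VAF 0.03
        } else if (mode[i] == 2L) {   # single caller
          evidence[j] <- "mutect:KEEP"
        } else {                      # flag mismatch
          evidence[j] <- "mutect:REJECT;strelka:PASS"
        }
      }
    }
    pos <- sample.int(max(1, round(exome_size_mb * 1e6)), n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt_allele <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    out <- data.frame(
      sample_id = sample_id,
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = pos,
      ref = ref,
      alt = alt_allele,
      gene = sprintf("GENE%03d", sample.int(500, n, replace = TRUE)),
      variant_classification = vc,
      distance_to_splice_site = NA_real_,
      caller_evidence = evidence,
      depth = depth,
      alt_count = alt,
      stringsAsFactors = FALSE
    )
    out$vaf <- out$alt_count / out$depth
    out$effect_class <- classify_effect(out$variant_classification,
                                        out$distance_to_splice_site)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cohort of sample-level metric values
#'
#' Draws per-group metric values i.i.d. from named distributions, producing
#' the cohort-table shape consumed by [compare_groups()] and
#' [summarize_medians()]. Supported distributions: `normal` (`mean`, `sd`),
#' `lognormal` (`meanlog`, `sdlog`), `beta` (`shape1`, `shape2`, optional
#' `scale` multiplying the draw), `gamma` (`shape`, `rate`).
#'
#' @param groups List of group specifications, each a list with `label`,
#'   `n` (>= 1), and `dist` (list with `name` and the distribution's
#'   parameters).
#' @param metric Name of the metric column (default `"ith"`).
#' @param group_field Name of the group column (default `"group"`).
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `group_field`, `metric`.
#' @examples
#' spec <- list(list(label = "a", n = 5, dist = list(name = "normal",
#'                                                   mean = 0, sd = 1)),
#'              list(label = "b", n = 5, dist = list(name = "normal",
#'                                                   mean = 1, sd = 1)))
#' simulate_cohort(spec, seed = 1)
#' @export
simulate_cohort <- function(groups, metric = "ith", group_field = "group",
                            seed = 1L) {
  stopifnot(length(groups) >= 1L)
  withr::with_seed(seed, {
    rows <- lapply(groups, function(g) {
      stopifnot(!is.null(g$label), !is.null(g$n), g$n >= 1L,
                !is.null(g$dist), !is.null(g$dist$name))
      d <- g$dist
      values <- switch(
        d$name,
        normal = stats::rnorm(g$n, d$mean, d$sd),
        lognormal = stats::rlnorm(g$n, d$meanlog, d$sdlog),
        beta = stats::rbeta(g$n, d$shape1, d$shape2) *
          (if (is.null(d$scale)) 1 else d$scale),
        gamma = stats::rgamma(g$n, shape = d$shape, rate = d$rate),
        stop("unknown distribution: ", d$name)
      )
      out <- data.frame(sample_id = paste0(g$label, "_", seq_len(g$n)),
                        group = g$label, value = values,
                        stringsAsFactors = FALSE)
      out
    })
    out <- do.call(rbind, rows)
    names(out)[names(out) == "group"] <- group_field
    names(out)[names(out) == "value"] <- metric
    rownames(out) <- NULL
    out
  })
}

#' Default disease-status cohort specification for ITH contrasts
#'
#' Group sizes and ITH distributions emulating a primary vs. recurrent vs.
#' metastasis contrast in a fusion-driven sarcoma cohort: 17 primary, 9
#' recurrent and 13 metastatic samples, with Shannon-ITH values drawn from
#' Beta distributions rescaled to `[0, ln 6]` (the attainable ITH range for
#' up to six subclones). Means are ordered primary < metastasis <
#' recurrent, with recurrent the most heterogeneous; the location shifts
#' (roughly 1.4-2 pooled standard deviations) reflect strongly significant
#' contrasts at these small group sizes.
#'
#' @param n_primary,n_recurrent,n_metastasis Group sizes.
#' @return A `groups` list for [simulate_cohort()].
#' @export
ith_status_cohort_spec <- function(n_primary = 17L, n_recurrent = 9L,
                                   n_metastasis = 13L) {
  scale <- log(6)
  list(
    list(label = "primary", n = n_primary,
         dist = list(name = "beta", shape1 = 2.0, shape2 = 6.0,
                     scale = scale)),
    list(label = "recurrent", n = n_recurrent,
         dist = list(name = "beta", shape1 = 5.0, shape2 = 4.0,
                     scale = scale)),
    list(label = "metastasis", n = n_metastasis,
         dist = list(name = "beta", shape1 = 4.0, shape2 = 4.5,
                     scale = scale))
  )
}
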