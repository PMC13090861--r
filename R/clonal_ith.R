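# Intratumoral heterogeneity pipeline: VAF -> cellular prevalence mapping,
# subclone clustering (ingested labels or built-in binomial-mixture EM),
# two-stage cluster merging, and the Shannon diversity index.

#' Map variant allele frequency to cellular prevalence
#'
#' Under the standard single-site model, a mutation present at multiplicity
#' `m` in tumor cells of local total copy number `C`, in a specimen of
#' purity `rho`, is observed at expected VAF
#' `rho * CP * m / (rho * C + 2 * (1 - rho))`. This function inverts that
#' mapping:
#' `CP = vaf * (rho * C + 2 * (1 - rho)) / (rho * m)`, clipped to `[0, 1]`.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param tumor_copy_number Local total copy number in tumor cells
#'   (default 2, heterozygous diploid).
#' @param multiplicity Mutation copies per tumor cell (default 1).
#' @return Cellular prevalence in `[0, 1]`.
#' @examples
#' vaf_to_cp(0.5, purity = 1)     # 1: clonal diploid limit
#' vaf_to_cp(0.25, purity = 0.5)  # 1
#' @export
vaf_to_cp <- function(vaf, purity, tumor_copy_number = 2L, multiplicity = 1L) {
  if (any(is.na(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("purity must lie in (0, 1]")
  }
  cp <- vaf * (purity * tumor_copy_number + 2 * (1 - purity)) /
    (purity * multiplicity)
  pmin(pmax(cp, 0), 1)
}

# expected VAF given CP (forward mapping; used by the simulator and EM init)
cp_to_vaf <- function(cp, purity, tumor_copy_number = 2L, multiplicity = 1L) {
  purity * cp * multiplicity / (purity * tumor_copy_number + 2 * (1 - purity))
}

#' Construct a set of clone clusters
#'
#' Bundles per-mutation cellular prevalence and VAF values with cluster
#' labels into the container consumed by [merge_stage1()], [merge_stage2()]
#' and [shannon_ith()]. Labels are opaque; each cluster must be non-empty.
#'
#' @param cp Numeric vector of per-mutation cellular prevalences.
#' @param vaf Numeric vector of per-mutation VAFs (same length).
#' @param cluster Vector of cluster labels (coerced to character).
#' @param mutation_id Optional mutation identifiers.
#' @return An object of class `clone_clusters`: list with elements `loci`
#'   (data frame `mutation_id`, `cp`, `vaf`, `cluster`) and `merge_log`
#'   (data frame of merge events, initially empty).
#' @export
clone_clusters <- function(cp, vaf, cluster, mutation_id = NULL) {
  stopifnot(length(cp) == length(vaf), length(cp) == length(cluster),
            length(cp) >= 1L)
  if (is.null(mutation_id)) mutation_id <- paste0("m", seq_along(cp))
  structure(
    list(
      loci = data.frame(mutation_id = as.character(mutation_id),
                        cp = as.numeric(cp), vaf = as.numeric(vaf),
                        cluster = as.character(cluster),
                        stringsAsFactors = FALSE),
      merge_log = empty_merge_log()
    ),
    class = "clone_clusters"
  )
}

empty_merge_log <- function() {
  data.frame(stage = character(0), merged = character(0), into = character(0),
             distance = numeric(0), p_cp = numeric(0), p_vaf = numeric(0),
             stringsAsFactors = FALSE)
}

#' Summarize clone clusters
#'
#' @param x A `clone_clusters` object.
#' @return Data frame with one row per cluster: `cluster`, `n`, `mean_cp`,
#'   `mean_vaf`, ordered by decreasing mean CP.
#' @export
cluster_summary <- function(x) {
  stopifnot(inherits(x, "clone_clusters"))
  loci <- x$loci
  labs <- unique(loci$cluster)
  s <- data.frame(
    cluster = labs,
    n = vapply(labs, function(l) sum(loci$cluster == l), integer(1L)),
    mean_cp = vapply(labs, function(l) mean(loci$cp[loci$cluster == l]),
                     numeric(1L)),
    mean_vaf = vapply(labs, function(l) mean(loci$vaf[loci$cluster == l]),
                      numeric(1L)),
    stringsAsFactors = FALSE
  )
  s <- s[order(-s$mean_cp, s$cluster), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' @export
print.clone_clusters <- function(x, ...) {
  s <- cluster_summary(x)
  cat("clone_clusters:", nrow(x$loci), "loci in", nrow(s), "cluster(s)\n")
  print(s, ...)
  invisible(x)
}

#' Built-in subclone clustering by binomial-mixture EM
#'
#' A desk-scale stand-in for an external Bayesian clonal-inference tool: a
#' one-dimensional mixture over allele fractions with a binomial read-count
#' emission per locus (`alt_i ~ Binomial(depth_i, theta_j)`), fitted by
#' expectation-maximization for `k = 1..k_max` components. Each `k` is
#' fitted from a deterministic multi-start schedule (quantile-spread
#' initializations plus seeded random restarts); `k` is selected by the
#' Bayesian information criterion and loci are assigned to their
#' maximum-responsibility component.
#'
#' @param loci Loci data frame with columns `vaf`, `alt_count`, and either
#'   `depth` or `ref_count`, plus `cellular_prevalence` (carried into the
#'   result as the per-locus CP).
#' @param k_max Maximum number of components (default 6).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param n_starts Random restarts per `k` in addition to the quantile
#'   initialization (default 3).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return A [clone_clusters()] object with components labeled
#'   `"1", "2", ...` in decreasing mean-CP order; the selected `k` and BIC
#'   table are attached as attributes `k` and `bic`.
#' @export
builtin_cluster <- function(loci, k_max = 6L, seed = 1L, n_starts = 3L,
                            max_iter = 500L, tol = 1e-8) {
  n <- nrow(loci)
  if (is.null(n) || n == 0L) stop("empty loci table")
  alt <- loci$alt_count
  depth <- if ("depth" %in% names(loci)) loci$depth else loci$ref_count + loci$alt_count
  if (anyNA(alt) || anyNA(depth)) {
    stop("builtin clustering needs per-locus read counts (alt_count and ",
         "ref_count or depth)")
  }
  vaf <- alt / depth
  fits <- withr::with_seed(seed, {
    lapply(seq_len(min(k_max, n)), function(k) {
      inits <- list(stats::quantile(vaf, probs = (seq_len(k) - 0.5) / k,
                                    names = FALSE, type = 8))
      for (i in seq_len(n_starts)) {
        inits[[i + 1L]] <- sort(sample(vaf, k, replace = TRUE) +
                                  stats::runif(k, -0.02, 0.02))
      }
      best <- NULL
      for (init in inits) {
        fit <- binom_mixture_em(alt, depth, init, max_iter, tol)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      best
    })
  })
  n_par <- vapply(seq_along(fits), function(k) 2 * k - 1, numeric(1L))
  bic <- -2 * vapply(fits, `[[`, numeric(1L), "loglik") + n_par * log(n)
  k_hat <- which.min(bic)
  fit <- fits[[k_hat]]
  assign_raw <- max.col(fit$resp, ties.method = "first")
  # relabel in decreasing component mean-VAF order, dropping empty components
  used <- sort(unique(assign_raw))
  ord <- used[order(-fit$theta[used])]
  assign <- match(assign_raw, ord)
  cp <- if ("cellular_prevalence" %in% names(loci)) {
    loci$cellular_prevalence
  } else {
    vaf  # caller maps to CP afterwards if needed
  }
  out <- clone_clusters(cp = cp, vaf = vaf, cluster = as.character(assign),
                        mutation_id = loci$mutation_id)
  attr(out, "k") <- length(used)
  attr(out, "bic") <- bic
  out
}

# EM for a k-component binomial mixture; theta = per-component allele
# fraction, w = mixing weights. Log-sum-exp for stability.
binom_mixture_em <- function(alt, depth, theta0, max_iter = 500L, tol = 1e-8) {
  theta <- pmin(pmax(theta0, 1e-6), 1 - 1e-6)
  k <- length(theta)
  n <- length(alt)
  w <- rep(1 / k, k)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    ll_mat <- vapply(seq_len(k), function(j) {
      stats::dbinom(alt, depth, theta[j], log = TRUE) + log(w[j])
    }, numeric(n))
    ll_mat <- matrix(ll_mat, nrow = n)
    mx <- apply(ll_mat, 1L, max)
    e <- exp(ll_mat - mx)
    rs <- rowSums(e)
    new_ll <- sum(mx + log(rs))
    resp <- e / rs
    w <- pmax(colMeans(resp), 1e-12)
    w <- w / sum(w)
    theta <- colSums(resp * alt) / pmax(colSums(resp * depth), 1e-12)
    theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  list(theta = theta, w = w, loglik = loglik, resp = resp)
}

#' Stage-1 cluster merging by average-linkage clustering
#'
#' Groups cluster centroids in the 2-D `(mean CP, mean VAF)` space by
#' average-linkage hierarchical clustering with Euclidean distance, cuts
#' the dendrogram at height `cutoff`, and merges clusters falling in the
#' same cut-group (members pooled, means recomputed). Designed to absorb
#' noise-prone singleton clusters into nearby clusters of similar CP and
#' VAF.
#'
#' @param x A [clone_clusters()] object.
#' @param cutoff Dendrogram cut height on the CP/VAF scale (default 0.05).
#' @param scope `"all"` (default) lets any clusters in a cut-group merge;
#'   `"singletons_only"` restricts merging so that clusters with more than
#'   one member are never merged with each other — singletons join the
#'   other clusters of their cut-group.
#' @param features `"cp_vaf"` (default, 2-D centroids) or `"cp"` (1-D, CP
#'   only).
#' @return The merged `clone_clusters` object; merge events are appended to
#'   `merge_log` with the maximum pairwise centroid distance of each merged
#'   group.
#' @export
merge_stage1 <- function(x, cutoff = 0.05,
                         scope = c("all", "singletons_only"),
                         features = c("cp_vaf", "cp")) {
  stopifnot(inherits(x, "clone_clusters"))
  scope <- match.arg(scope)
  features <- match.arg(features)
  s <- cluster_summary(x)
  if (nrow(s) < 2L) return(x)
  cent <- if (features == "cp_vaf") {
    cbind(s$mean_cp, s$mean_vaf)
  } else {
    cbind(s$mean_cp)
  }
  rownames(cent) <- s$cluster
  d <- stats::dist(cent, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, h = cutoff)
  dmat <- as.matrix(d)
  for (g in unique(grp)) {
    labs <- s$cluster[grp == g]
    if (length(labs) < 2L) next
    if (scope == "singletons_only") {
      singles <- labs[s$n[match(labs, s$cluster)] == 1L]
      multis <- setdiff(labs, singles)
      if (length(singles) == 0L) next
      if (length(multis) > 1L) {
        # attach each singleton to its nearest multi-member cluster
        for (sl in singles) {
          target <- multis[which.min(dmat[sl, multis])]
          x <- apply_merge(x, c(sl, target), stage = "stage1",
                           distance = dmat[sl, target])
        }
        next
      }
      labs <- c(singles, multis)
    }
    x <- apply_merge(x, labs, stage = "stage1",
                     distance = max(dmat[labs, labs]))
  }
  x
}

# Pool the named clusters under the lexicographically smallest label and log
# the event.
apply_merge <- function(x, labs, stage, distance = NA_real_,
                        p_cp = NA_real_, p_vaf = NA_real_) {
  labs <- sort(unique(as.character(labs)))
  into <- labs[1L]
  x$loci$cluster[x$loci$cluster %in% labs] <- into
  x$merge_log <- rbind(x$merge_log, data.frame(
    stage = stage, merged = paste(labs, collapse = ","), into = into,
    distance = distance, p_cp = p_cp, p_vaf = p_vaf,
    stringsAsFactors = FALSE
  ))
  x
}

#' Stage-2 cluster merging by pairwise rank-sum refinement
#'
#' Iterative agglomeration: at each round, every unordered cluster pair is
#' compared with the two-sided rank-sum test on member CP values and,
#' separately, on member VAF values. A pair is mergeable when both
#' p-values exceed `alpha` (strict inequality), i.e. when the two clusters
#' show no significant difference in either CP or VAF. Among mergeable
#' pairs, the one with the largest minimum of its two p-values is merged
#' (ties broken by larger p-value sum, then smaller centroid distance, then
#' lexicographic labels); means are recomputed and the round repeats until
#' no pair is mergeable. The procedure is idempotent — a second application
#' performs no merges.
#'
#' @param x A [clone_clusters()] object.
#' @param alpha Significance threshold (default 0.05); clusters merge only
#'   when both p-values are `> alpha`.
#' @param exact_max_n Passed to [ranksum_test()].
#' @return The merged `clone_clusters` object with both p-values of every
#'   merge appended to `merge_log`.
#' @export
merge_stage2 <- function(x, alpha = 0.05, exact_max_n = 10L) {
  stopifnot(inherits(x, "clone_clusters"))
  repeat {
    s <- cluster_summary(x)
    k <- nrow(s)
    if (k < 2L) break
    labs <- s$cluster
    members <- lapply(labs, function(l) x$loci[x$loci$cluster == l, ])
    names(members) <- labs
    pairs <- utils::combn(labs, 2L)
    best <- NULL
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      p_cp <- ranksum_test(members[[a]]$cp, members[[b]]$cp,
                           exact_max_n)$p_value
      p_vaf <- ranksum_test(members[[a]]$vaf, members[[b]]$vaf,
                            exact_max_n)$p_value
      if (!(p_cp > alpha && p_vaf > alpha)) next
      ia <- match(a, labs); ib <- match(b, labs)
      dist_ab <- sqrt((s$mean_cp[ia] - s$mean_cp[ib])^2 +
                        (s$mean_vaf[ia] - s$mean_vaf[ib])^2)
      cand <- list(a = a, b = b, p_cp = p_cp, p_vaf = p_vaf,
                   minp = min(p_cp, p_vaf), sump = p_cp + p_vaf,
                   dist = dist_ab)
      if (is.null(best) ||
          cand$minp > best$minp ||
          (cand$minp == best$minp && cand$sump > best$sump) ||
          (cand$minp == best$minp && cand$sump == best$sump &&
             cand$dist < best$dist) ||
          (cand$minp == best$minp && cand$sump == best$sump &&
             cand$dist == best$dist &&
             paste(cand$a, cand$b) < paste(best$a, best$b))) {
        best <- cand
      }
    }
    if (is.null(best)) break
    x <- apply_merge(x, c(best$a, best$b), stage = "stage2",
                     distance = best$dist, p_cp = best$p_cp,
                     p_vaf = best$p_vaf)
  }
  x
}

#' Shannon diversity index of the subclonal composition
#'
#' Computes the per-sample intratumoral heterogeneity score: the mean CP of
#' each cluster is normalized to a relative proportion
#' `p_i = mean_cp_i / sum_j mean_cp_j` and the Shannon index
#' `H' = -sum p_i ln(p_i)` is evaluated in natural-log units (nats).
#' A single cluster yields exactly 0; `k` equal-CP clusters yield `ln k`.
#' Clusters with mean CP of 0 are dropped with a warning before
#' normalization (the formula is undefined at `p = 0`); if all clusters
#' have zero CP, an error is raised.
#'
#' @param x A [clone_clusters()] object (typically after [merge_stage1()]
#'   and [merge_stage2()]).
#' @param sample_id Optional sample label carried into the result.
#' @param provenance `"ingested"` or `"builtin_clustering"`.
#' @return An object of class `clonal_structure`: list with `sample_id`,
#'   `clusters` (the [cluster_summary()] table), `proportions`,
#'   `ith_score`, `provenance`, `merge_log`.
#' @examples
#' x <- clone_clusters(cp = c(0.8, 0.8, 0.2, 0.2), vaf = c(0.4, 0.4, 0.1, 0.1),
#'                     cluster = c("a", "a", "b", "b"))
#' shannon_ith(x)$ith_score  # -(0.8 ln 0.8 + 0.2 ln 0.2) approx. 0.5004
#' @export
shannon_ith <- function(x, sample_id = NA_character_,
                        provenance = c("ingested", "builtin_clustering")) {
  stopifnot(inherits(x, "clone_clusters"))
  provenance <- match.arg(provenance)
  s <- cluster_summary(x)
  if (any(s$mean_cp == 0)) {
    if (all(s$mean_cp == 0)) stop("all clusters have mean CP 0")
    warning("dropping ", sum(s$mean_cp == 0),
            " cluster(s) with mean CP 0 before Shannon normalization")
    s <- s[s$mean_cp > 0, , drop = FALSE]
  }
  p <- s$mean_cp / sum(s$mean_cp)
  ith <- if (nrow(s) == 1L) 0 else -sum(p * log(p))
  structure(
    list(sample_id = sample_id, clusters = s, proportions = p,
         ith_score = ith, provenance = provenance, merge_log = x$merge_log),
    class = "clonal_structure"
  )
}

#' @export
print.clonal_structure <- function(x, ...) {
  cat("clonal_structure",
      if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]") else "",
      "\n  clusters:", nrow(x$clusters),
      " ITH (Shannon, nats):", format(x$ith_score, digits = 4),
      " provenance:", x$provenance, "\n")
  invisible(x)
}

#' Run the full ITH pipeline for one sample
#'
#' End-to-end per-sample heterogeneity scoring: cluster assignments are
#' taken from the loci table's `cluster_id` column when present
#' (provenance `"ingested"`, the fidelity path for an external
#' clonal-inference tool) or computed with [builtin_cluster()]; clusters
#' are then refined by [merge_stage1()] and [merge_stage2()] and scored
#' with [shannon_ith()]. Samples without a known tumor purity are not
#' scored: purity is required to map VAF to cellular prevalence.
#'
#' @param loci Loci data frame for one sample (see [read_loci_table()] or
#'   [simulate_subclonal_tumor()]).
#' @param purity Tumor purity in `(0, 1]`; an `NA` raises an error so the
#'   caller can exclude and report the sample.
#' @param cutoff Stage-1 merge cutoff (default 0.05).
#' @param alpha Stage-2 rank-sum threshold (default 0.05).
#' @param k_max Maximum component count for built-in clustering.
#' @param seed Seed for built-in clustering.
#' @param use_ingested Use the `cluster_id` column when available (default
#'   `TRUE`); set `FALSE` to force built-in clustering.
#' @param stage1_scope,stage1_features Passed to [merge_stage1()].
#' @param tumor_copy_number,multiplicity Passed to [vaf_to_cp()] when the
#'   loci table lacks a `cellular_prevalence` column.
#' @return A `clonal_structure` object (see [shannon_ith()]).
#' @export
run_ith_pipeline <- function(loci, purity,
                             cutoff = 0.05, alpha = 0.05,
                             k_max = 6L, seed = 1L,
                             use_ingested = TRUE,
                             stage1_scope = "all",
                             stage1_features = "cp_vaf",
                             tumor_copy_number = 2L, multiplicity = 1L) {
  if (is.null(loci) || nrow(loci) == 0L) stop("empty loci table")
  if (length(purity) != 1L || is.na(purity)) {
    stop("sample excluded: tumor purity is required for ITH scoring")
  }
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  sample_id <- if ("sample_id" %in% names(loci)) loci$sample_id[1L] else NA_character_
  if (!("cellular_prevalence" %in% names(loci)) ||
      anyNA(loci$cellular_prevalence)) {
    loci$cellular_prevalence <- vaf_to_cp(loci$vaf, purity,
                                          tumor_copy_number, multiplicity)
  }
  ingested <- use_ingested && "cluster_id" %in% names(loci) &&
    !anyNA(loci$cluster_id)
  if (ingested) {
    x <- clone_clusters(cp = loci$cellular_prevalence, vaf = loci$vaf,
                        cluster = loci$cluster_id,
                        mutation_id = loci$mutation_id)
    provenance <- "ingested"
  } else {
    x <- builtin_cluster(loci, k_max = k_max, seed = seed)
    provenance <- "builtin_clustering"
  }
  n_initial <- nrow(cluster_summary(x))
  x <- merge_stage1(x, cutoff = cutoff, scope = stage1_scope,
                    features = stage1_features)
  n_stage1 <- nrow(cluster_summary(x))
  x <- merge_stage2(x, alpha = alpha)
  n_stage2 <- nrow(cluster_summary(x))
  res <- shannon_ith(x, sample_id = sample_id, provenance = provenance)
  res$n_clusters <- c(initial = n_initial, after_stage1 = n_stage1,
                      after_stage2 = n_stage2)
  res
}

#' Run the ITH pipeline across a cohort
#'
#' Applies [run_ith_pipeline()] to every sample of a multi-sample loci
#' table, taking purity from the cohort metadata. Samples absent from the
#' metadata or lacking purity are excluded and reported, mirroring the
#' requirement that only samples with available tumor purity are scored.
#'
#' @param loci Multi-sample loci data frame.
#' @param metadata Cohort data frame with `sample_id` and `purity` columns.
#' @param ... Passed to [run_ith_pipeline()].
#' @return List with `summary` (data frame: `sample_id`,
#'   `n_clusters_initial`, `n_after_stage1`, `n_after_stage2`, `ith_score`,
#'   `provenance`), `structures` (named list of `clonal_structure`
#'   objects), and `excluded` (data frame `sample_id`, `reason`).
#' @export
run_ith_cohort <- function(loci, metadata, ...) {
  samples <- unique(loci$sample_id)
  structures <- list()
  excluded <- data.frame(sample_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (s in samples) {
    purity <- metadata$purity[match(s, metadata$sample_id)]
    if (length(purity) == 0L || is.na(purity)) {
      excluded <- rbind(excluded,
                        data.frame(sample_id = s, reason = "missing purity",
                                   stringsAsFactors = FALSE))
      next
    }
    structures[[s]] <- run_ith_pipeline(loci[loci$sample_id == s, ],
                                        purity = purity, ...)
  }
  if (nrow(excluded) > 0L) {
    message(nrow(excluded), " sample(s) excluded from ITH scoring: ",
            paste(excluded$sample_id, collapse = ", "))
  }
  summary <- do.call(rbind, lapply(names(structures), function(s) {
    st <- structures[[s]]
    data.frame(sample_id = s,
               n_clusters_initial = st$n_clusters[["initial"]],
               n_after_stage1 = st$n_clusters[["after_stage1"]],
               n_after_stage2 = st$n_clusters[["after_stage2"]],
               ith_score = st$ith_score,
               provenance = st$provenance,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(sample_id = character(0),
                          n_clusters_initial = integer(0),
                          n_after_stage1 = integer(0),
                          n_after_stage2 = integer(0),
                          ith_score = numeric(0),
                          provenance = character(0),
                          stringsAsFactors = FALSE)
  }
  list(summary = summary, structures = structures, excluded = excluded)
}
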