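# CP mapping, built-in clustering, two-stage merging, Shannon index,
# and the end-to-end per-sample pipeline.

test_that("VAF to CP mapping evaluates and clips correctly", {
  expect_equal(vaf_to_cp(0.5, purity = 1), 1)
  expect_equal(vaf_to_cp(0.25, purity = 0.5), 1)
  expect_equal(vaf_to_cp(0, purity = 0.3), 0)
  expect_equal(vaf_to_cp(0.9, purity = 1), 1)       # clipped
  expect_equal(vaf_to_cp(0.2, purity = 1, tumor_copy_number = 4,
                         multiplicity = 2), 0.4)
  expect_error(vaf_to_cp(0.5, purity = 0), "purity")
})

test_that("Shannon index: analytic limits and the worked two-cluster case", {
  one <- clone_clusters(cp = c(0.4, 0.5), vaf = c(0.2, 0.25),
                        cluster = c("a", "a"))
  expect_identical(shannon_ith(one)$ith_score, 0)

  two_equal <- clone_clusters(cp = rep(0.6, 4), vaf = rep(0.3, 4),
                              cluster = c("a", "a", "b", "b"))
  expect_equal(shannon_ith(two_equal)$ith_score, log(2), tolerance = 1e-12)

  skewed <- clone_clusters(cp = c(0.8, 0.2), vaf = c(0.4, 0.1),
                           cluster = c("a", "b"))
  expect_equal(shannon_ith(skewed)$ith_score,
               -(0.8 * log(0.8) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(shannon_ith(skewed)$ith_score, 0.5004, tolerance = 1e-4)
})

test_that("Shannon normalization: proportions sum to 1, zero-CP clusters drop", {
  x <- clone_clusters(cp = c(0.9, 0.3, 0.1), vaf = c(0.45, 0.15, 0.05),
                      cluster = c("a", "b", "c"))
  st <- shannon_ith(x)
  expect_equal(sum(st$proportions), 1, tolerance = 1e-9)
  expect_lte(st$ith_score, log(3) + 1e-9)

  with_zero <- clone_clusters(cp = c(0.8, 0), vaf = c(0.4, 0),
                              cluster = c("a", "b"))
  expect_warning(st0 <- shannon_ith(with_zero), "mean CP 0")
  expect_identical(st0$ith_score, 0)
  all_zero <- clone_clusters(cp = c(0, 0), vaf = c(0, 0),
                             cluster = c("a", "b"))
  expect_error(shannon_ith(all_zero), "all clusters")
})

test_that("ITH is invariant to cluster relabeling and locus order", {
  set.seed(12)
  x <- random_clone_clusters(k = 3)
  base <- shannon_ith(x)$ith_score
  relab <- x
  relab$loci$cluster <- c(`1` = "zz", `2` = "q", `3` = "07")[relab$loci$cluster]
  expect_equal(shannon_ith(relab)$ith_score, base, tolerance = 1e-12)
  shuf <- x
  shuf$loci <- shuf$loci[sample(nrow(shuf$loci)), ]
  expect_equal(shannon_ith(shuf)$ith_score, base, tolerance = 1e-12)
})

test_that("stage-1 merging follows the centroid-distance cutoff", {
  # singleton at (0.50, 0.25) and cluster at (0.52, 0.26): distance 0.0224 < 0.05
  x <- clone_clusters(cp = c(0.50, 0.52, 0.52), vaf = c(0.25, 0.26, 0.26),
                      cluster = c("s", "c", "c"))
  merged <- merge_stage1(x)
  expect_equal(nrow(cluster_summary(merged)), 1L)
  expect_equal(merged$merge_log$stage, "stage1")
  expect_equal(merged$merge_log$distance, sqrt(0.02^2 + 0.01^2),
               tolerance = 1e-9)

  # (0.2, 0.1) vs (0.8, 0.4): distance 0.6708, far above the cutoff
  far <- clone_clusters(cp = c(0.2, 0.8), vaf = c(0.1, 0.4),
                        cluster = c("a", "b"))
  expect_equal(nrow(cluster_summary(merge_stage1(far))), 2L)

  single <- clone_clusters(cp = 0.5, vaf = 0.25, cluster = "a")
  expect_identical(merge_stage1(single)$loci, single$loci)
})

test_that("stage-1 singletons_only scope never merges two multi-member clusters", {
  x <- clone_clusters(cp = c(0.50, 0.50, 0.52, 0.52, 0.51),
                      vaf = c(0.25, 0.25, 0.26, 0.26, 0.255),
                      cluster = c("a", "a", "b", "b", "s"))
  all_mode <- merge_stage1(x, scope = "all")
  expect_equal(nrow(cluster_summary(all_mode)), 1L)
  restricted <- merge_stage1(x, scope = "singletons_only")
  s <- cluster_summary(restricted)
  expect_equal(nrow(s), 2L)        # a and b survive; the singleton joined one
  expect_true(all(s$n >= 2L))
})

test_that("stage-2 merges identical clusters and keeps separated ones apart", {
  same <- clone_clusters(cp = rep(c(0.5, 0.6), 2), vaf = rep(c(0.25, 0.3), 2),
                         cluster = rep(c("a", "b"), each = 2))
  m <- merge_stage2(same)
  expect_equal(nrow(cluster_summary(m)), 1L)
  expect_equal(m$merge_log$p_cp, 1)
  expect_equal(m$merge_log$p_vaf, 1)

  apart <- clone_clusters(cp = c(seq(0.10, 0.17, 0.01), seq(0.80, 0.87, 0.01)),
                          vaf = c(seq(0.05, 0.085, 0.005), seq(0.40, 0.435, 0.005)),
                          cluster = rep(c("lo", "hi"), each = 8))
  expect_equal(nrow(cluster_summary(merge_stage2(apart))), 2L)

  single <- clone_clusters(cp = 0.5, vaf = 0.25, cluster = "a")
  expect_identical(merge_stage2(single)$loci, single$loci)
})

test_that("stage-2 requires BOTH CP and VAF to be non-significant", {
  set.seed(5)
  # same CP distribution, clearly different VAF distribution
  cp <- rep(seq(0.4, 0.6, length.out = 6), 2)
  vaf <- c(seq(0.10, 0.15, length.out = 6), seq(0.40, 0.45, length.out = 6))
  x <- clone_clusters(cp = cp, vaf = vaf, cluster = rep(c("a", "b"), each = 6))
  expect_equal(nrow(cluster_summary(merge_stage2(x))), 2L)
})

test_that("merging conserves loci and never increases cluster count", {
  set.seed(21)
  for (i in 1:25) {
    x <- random_clone_clusters()
    n0 <- nrow(x$loci)
    k0 <- nrow(cluster_summary(x))
    m1 <- merge_stage1(x)
    expect_equal(nrow(m1$loci), n0)
    expect_lte(nrow(cluster_summary(m1)), k0)
    m2 <- merge_stage2(m1)
    expect_equal(nrow(m2$loci), n0)
    expect_lte(nrow(cluster_summary(m2)), nrow(cluster_summary(m1)))
    expect_setequal(m2$loci$mutation_id, x$loci$mutation_id)
  }
})

test_that("stage-2 is idempotent", {
  set.seed(33)
  for (i in 1:30) {
    x <- merge_stage2(random_clone_clusters())
    log_before <- nrow(x$merge_log)
    again <- merge_stage2(x)
    expect_equal(nrow(again$merge_log), log_before)
    expect_identical(cluster_summary(again), cluster_summary(x))
  }
})

test_that("built-in clustering recovers simulated subclone structure", {
  one <- simulate_subclonal_tumor(0.9, 100, purity = 1, mean_depth = 500,
                                  seed = 51)
  fit1 <- builtin_cluster(one$loci, seed = 1)
  expect_equal(attr(fit1, "k"), 1L)

  two <- simulate_subclonal_tumor(c(0.9, 0.3), c(50, 50), purity = 1,
                                  mean_depth = 500, seed = 52)
  fit2 <- builtin_cluster(two$loci, seed = 1)
  expect_equal(attr(fit2, "k"), 2L)
  # assignment accuracy >= 95% up to label permutation
  truth <- two$loci$cluster_id
  got <- as.integer(fit2$loci$cluster)
  acc <- max(mean(got == truth), mean(got == 3L - truth))
  expect_gte(acc, 0.95)

  lone <- simulate_subclonal_tumor(0.5, 1, seed = 53)
  fit_lone <- builtin_cluster(lone$loci, seed = 1)
  expect_equal(nrow(cluster_summary(fit_lone)), 1L)
  expect_error(builtin_cluster(lone$loci[0, ], seed = 1), "empty")
})

test_that("built-in clustering is deterministic given the seed", {
  sim <- simulate_subclonal_tumor(c(0.8, 0.4), c(30, 30), seed = 60)
  a <- builtin_cluster(sim$loci, seed = 9)
  b <- builtin_cluster(sim$loci, seed = 9)
  expect_identical(a$loci, b$loci)
  expect_identical(attr(a, "bic"), attr(b, "bic"))
})

test_that("pipeline: pre-assigned single cluster gives ITH 0 and ingested provenance", {
  sim <- simulate_subclonal_tumor(0.8, 30, seed = 71)
  loci <- sim$loci
  loci$cluster_id <- 1L
  st <- run_ith_pipeline(loci, purity = 1)
  expect_identical(st$ith_score, 0)
  expect_equal(st$provenance, "ingested")
})

test_that("pipeline recovers a three-subclone tumor's structure and ITH", {
  sim <- simulate_subclonal_tumor(c(1.0, 0.6, 0.2), c(40, 40, 40),
                                  purity = 1, mean_depth = 500, seed = 81)
  st <- run_ith_pipeline(sim$loci, purity = 1, use_ingested = FALSE)
  expect_equal(nrow(st$clusters), 3L)
  expect_equal(st$ith_score, sim$truth$ith_true, tolerance = 0.1)
  expect_equal(st$provenance, "builtin_clustering")
  expect_equal(sum(st$proportions), 1, tolerance = 1e-9)
})

test_that("samples without purity are excluded with a report", {
  sim <- simulate_subclonal_tumor(c(0.9, 0.3), c(20, 20), seed = 91)
  expect_error(run_ith_pipeline(sim$loci, purity = NA), "excluded")

  other <- simulate_subclonal_tumor(0.7, 15, seed = 92, sample_id = "sim2")
  loci <- rbind(sim$loci, other$loci)
  meta <- data.frame(sample_id = c("sim1", "sim2"), purity = c(0.8, NA),
                     stringsAsFactors = FALSE)
  res <- suppressMessages(run_ith_cohort(loci, meta, use_ingested = TRUE))
  expect_equal(res$summary$sample_id, "sim1")
  expect_equal(res$excluded$sample_id, "sim2")
  expect_equal(res$excluded$reason, "missing purity")
})
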