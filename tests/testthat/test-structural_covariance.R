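test_that("group_covariance is a valid correlation matrix", {
  des <- data.frame(subject_id = c("s1", "s2", "s3"),
                    sex = "M", group = "treated")
  vols <- cbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(9, 3, 5))
  rownames(vols) <- des$subject_id
  vt <- volume_table(des, vols)
  hier <- atlas_hierarchy(data.frame(
    region_id = c("A", "B", "C"),
    area = "other",
    cluster = c("posterior_cortical", "posterior_cortical", "hippocampal")))
  gc <- group_covariance(vt, hier, group = "treated")
  expect_equal(gc$r["A", "B"], 1)                 # exact collinearity
  expect_identical(gc$r, t(gc$r))
  expect_equal(unname(diag(gc$r)), rep(1, 3))
  expect_true(all(gc$r >= -1 & gc$r <= 1))
  expect_equal(gc$n_subjects, 3L)

  # < 3 subjects is an error
  expect_error(group_covariance(vt, hier, subjects = c("s1", "s2")),
               ">= 3 subjects")

  # zero-variance region flagged and excluded
  vols2 <- cbind(vols, D = c(7, 7, 7))
  hier2 <- atlas_hierarchy(data.frame(
    region_id = c("A", "B", "C", "D"), area = "other",
    cluster = c("posterior_cortical", "posterior_cortical",
                "hippocampal", "hippocampal")))
  vt2 <- volume_table(des, vols2)
  expect_warning(gc2 <- group_covariance(vt2, hier2, group = "treated"),
                 "zero-variance")
  expect_identical(gc2$dropped, "D")
  expect_false("D" %in% gc2$regions)

  # unassigned regions are excluded
  hier3 <- atlas_hierarchy(data.frame(
    region_id = c("A", "B", "C"), area = "other",
    cluster = c("posterior_cortical", "posterior_cortical", "")))
  gc3 <- group_covariance(vt, hier3, group = "treated")
  expect_identical(gc3$regions, c("A", "B"))
})

test_that("cluster block extraction follows both conventions", {
  set.seed(8)
  k <- 5
  z <- matrix(rnorm(40 * k), 40, k)
  r <- cor(z)
  dimnames(r) <- list(paste0("p", 1:k), paste0("p", 1:k))
  gc <- make_gc(r, clusters = c(rep("posterior_cortical", 3),
                                rep("hippocampal", 2)))
  intra <- cluster_block_values(gc, "posterior_cortical")
  expect_length(intra, 9)                       # 3 x 3 Cartesian
  expect_equal(sum(intra == 1), 3)              # three self-correlations
  expect_length(cluster_block_values(gc, "posterior_cortical",
                                     convention = "unique"), 3)
  inter <- cluster_block_values(gc, "posterior_cortical", "hippocampal")
  expect_length(inter, 6)                       # 3 x 2 either way
  expect_length(cluster_block_values(gc, "posterior_cortical", "hippocampal",
                                     convention = "unique"), 6)
  expect_error(cluster_block_values(gc, "cortex"), "unknown cluster")
  expect_error(cluster_block_values(gc, "midbrain"), "no regions")

  # identity block: Cartesian mean is k/k^2
  gi <- make_gc(diag(3), clusters = rep("midbrain", 3))
  rownames(gi$r) <- colnames(gi$r) <- paste0("m", 1:3)
  gi$regions <- paste0("m", 1:3)
  names(gi$cluster) <- gi$regions
  expect_equal(mean_block_correlation(
    cluster_block_values(gi, "midbrain")), 1 / 3)
})

test_that("Cartesian and unique intra-block means obey the algebraic identity", {
  set.seed(19)
  for (k in c(3, 5, 8)) {
    z <- matrix(rnorm(30 * k), 30, k)
    r <- cor(z)
    dimnames(r) <- list(paste0("g", 1:k), paste0("g", 1:k))
    gc <- make_gc(r, clusters = rep("subcortical", k))
    paper <- cluster_block_values(gc, "subcortical")
    uniq <- cluster_block_values(gc, "subcortical", convention = "unique")
    # mean_paper = (k + 2 * sum_{i<j} r_ij) / k^2
    expect_equal(mean(paper), (k + 2 * sum(uniq)) / k^2)
  }
})

test_that("mean_block_correlation averages raw r; Fisher variant differs", {
  expect_equal(mean_block_correlation(c(0.2, 0.4)), 0.3)
  expect_equal(mean_block_correlation(rep(0.55, 7)), 0.55)
  expect_error(mean_block_correlation(numeric(0)), "empty")
  set.seed(4)
  v <- runif(50, -0.8, 0.8)
  raw <- mean_block_correlation(v)
  fz <- mean_block_correlation(v, fisher = TRUE)
  # tanh is concave on positive z: numeric check of the Jensen relation
  expect_equal(fz, tanh(mean(atanh(v))))
})

test_that("kruskal_wallis matches the worked example and stats::kruskal.test", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$H, 27 / 7)              # hand ranking: 12/42*87 - 21
  expect_equal(res$eta_squared, 5 / 7)     # (27/7 - 1) / 4
  expect_equal(res$p, pchisq(27 / 7, 1, lower.tail = FALSE))

  # all values identical: H = 0 after the tie-correction guard
  res0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(res0$H, 0)
  expect_equal(res0$eta_squared, 0)

  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      x <- rnorm(sample(3:9, 1))
      if (i %% 2 == 0) round(x)  # force ties half the time
      else x
    })
    mine <- kruskal_wallis(groups)
    ref <- kruskal.test(unlist(groups),
                        factor(rep(seq_len(k), lengths(groups))))
    expect_equal(mine$H, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
  }
})

test_that("exact permutation p agrees with chi-square at moderate H", {
  g <- list(c(0.3, 1.2, 0.8), c(2.1, 1.9, 2.6))
  ex <- kruskal_wallis(g, exact = TRUE)
  ap <- kruskal_wallis(g)
  expect_true(ex$p >= 0 && ex$p <= 1)
  expect_equal(ex$H, ap$H)
  # the exact p for complete separation of 3 vs 3 is 2 / choose(6,3) = 0.1
  expect_equal(ex$p, 0.1)
})

test_that("eta-squared large-effect call uses a strict threshold", {
  expect_true(covmorph:::is_large_effect(0.15))
  expect_false(covmorph:::is_large_effect(0.14))
  expect_false(covmorph:::is_large_effect(0.14 - 1e-12))
})

test_that("classify_effect distinguishes treatment and sex patterns", {
  set.seed(23)
  jitter0 <- function(mu, n = 60) mu + runif(n, -0.02, 0.02)
  ctlM <- jitter0(0.30); ctlF <- jitter0(0.30)
  # uniform treatment shift, treated cells literally identical
  trt <- jitter0(-0.10)
  cls <- classify_effect(list(treated.M = trt, treated.F = trt,
                              control.M = ctlM, control.F = ctlF))
  expect_equal(cls$effect_class, "treatment")
  # male-treated-only shift
  cls2 <- classify_effect(list(treated.M = jitter0(-0.10),
                               treated.F = jitter0(0.30),
                               control.M = ctlM, control.F = ctlF))
  expect_equal(cls2$effect_class, "sex_within_treated")
  # both: treatment shift plus a sex difference within treated
  cls3 <- classify_effect(list(treated.M = jitter0(-0.20),
                               treated.F = jitter0(-0.05),
                               control.M = ctlM, control.F = ctlF))
  expect_equal(cls3$effect_class, "both")
  # nothing going on: four identical distributions
  cls4 <- classify_effect(list(treated.M = ctlM, treated.F = ctlM,
                               control.M = ctlM, control.F = ctlM))
  expect_equal(cls4$effect_class, "none")
})

test_that("compare_blocks_across_groups validates inputs and is order-safe", {
  sim <- simulate_cohort(paper_scenario(seed = 5))
  covs <- covariance_by_cell(sim$vt, sim$hierarchy)
  res <- suppressWarnings(compare_blocks_across_groups(covs))
  expect_equal(nrow(res), 21)
  expect_true(all(res$eta_squared >= 0))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(res$effect_class %in%
                    c("treatment", "sex_within_treated", "both", "none")))
  # classification skipped when the omnibus fails
  expect_true(all(res$effect_class[!res$omnibus_pass] == "none"))
  # group order must not matter
  res2 <- suppressWarnings(compare_blocks_across_groups(covs[c(3, 1, 4, 2)]))
  expect_equal(res2$H, res$H)
  expect_equal(res2$effect_class, res$effect_class)
  # region-set mismatch is an error
  covs_bad <- covs
  covs_bad[[1]]$regions <- covs_bad[[1]]$regions[-1]
  expect_error(suppressWarnings(compare_blocks_across_groups(covs_bad)),
               "region sets differ")
  expect_error(suppressWarnings(compare_blocks_across_groups(covs[1:3])),
               "four")
})

test_that("block statistics are invariant to region relabeling", {
  sim <- simulate_cohort(paper_scenario(seed = 6))
  vt <- sim$vt
  perm <- sample(length(vt$regions))
  vt_p <- volume_table(vt$design, vt$volumes[, perm])
  g1 <- group_covariance(vt, sim$hierarchy, sex = "F", group = "control")
  g2 <- group_covariance(vt_p, sim$hierarchy, sex = "F", group = "control")
  v1 <- sort(cluster_block_values(g1, "hippocampal", "midbrain"))
  v2 <- sort(cluster_block_values(g2, "hippocampal", "midbrain"))
  expect_equal(v1, v2)
})
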