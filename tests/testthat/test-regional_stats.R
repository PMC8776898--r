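test_that("cohens_d matches hand computation and is antisymmetric", {
  # pooled SD of {1,2,3} and {3,4,5} is 1, mean difference -2
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(5)
  x <- rnorm(8); y <- rnorm(6)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "degenerate")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("compare_tbv equals the sum-of-squares oracle", {
  # cells {1,2,3} x3 and {7,8,9}: SSB = 81 (df 3), SSW = 8 (df 8), F = 27
  des <- data.frame(subject_id = sprintf("s%d", 1:12),
                    sex = rep(c("M", "F"), each = 6),
                    group = rep(c("treated", "control", "treated", "control"),
                                each = 3))
  vols <- cbind(a = c(1, 2, 3, 1, 2, 3, 1, 2, 3, 7, 8, 9))
  rownames(vols) <- des$subject_id
  vt <- volume_table(des, vols)
  res <- compare_tbv(vt)
  expect_equal(res$F, 27)
  expect_equal(res$p, pf(27, 3, 8, lower.tail = FALSE))
  expect_equal(nrow(res$pairwise), 6)
})

test_that("compare_tbv edge cases: identical cells and ANOVA-t identity", {
  des <- data.frame(subject_id = sprintf("s%d", 1:8),
                    sex = rep(c("M", "M", "F", "F"), 2),
                    group = rep(c("treated", "control"), each = 4))
  vols <- cbind(a = rep(c(1, 2), 4))
  rownames(vols) <- des$subject_id
  vt <- volume_table(des, vols)  # all four cells are {1, 2}
  res <- compare_tbv(vt)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p_adj == 1))

  # two occupied cells: F equals the squared pooled-t statistic
  des2 <- data.frame(subject_id = sprintf("s%d", 1:10),
                     sex = "M",
                     group = rep(c("treated", "control"), each = 5))
  set.seed(9)
  vols2 <- cbind(a = rnorm(10, mean = rep(c(10, 12), each = 5)))
  rownames(vols2) <- des2$subject_id
  vt2 <- volume_table(des2, vols2)
  res2 <- compare_tbv(vt2)
  tt <- t.test(vols2[1:5], vols2[6:10], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2)

  # a cell with < 2 subjects is an error
  expect_error(compare_tbv(make_vt(c(treated.M = 1, treated.F = 3,
                                     control.M = 3, control.F = 3))),
               "fewer than 2")
})

test_that("regionwise_compare is scale-equivariant and handles degeneracy", {
  vt <- make_vt(n_per_cell = c(treated.M = 5, treated.F = 5,
                               control.M = 5, control.F = 5), seed = 21)
  r1 <- regionwise_compare(vt, "full")
  vt2 <- volume_table(vt$design, vt$volumes * 2)
  r2 <- regionwise_compare(vt2, "full")
  expect_equal(r2$p, r1$p)
  expect_equal(r2$q, r1$q)
  expect_equal(r2$cohens_d, r1$cohens_d)
  expect_equal(r2$mean_diff, 2 * r1$mean_diff)
  # relative measure: mean differences unchanged under global doubling
  rel1 <- regionwise_compare(vt, "full", measure = "relative")
  rel2 <- regionwise_compare(vt2, "full", measure = "relative")
  expect_equal(rel2$mean_diff, rel1$mean_diff)
  expect_equal(rel2$p, rel1$p)

  # identical treated and control values: diff 0, d 0, p 1
  des <- data.frame(subject_id = sprintf("s%d", 1:8),
                    sex = rep(c("M", "F"), 4),
                    group = rep(c("treated", "control"), each = 4))
  vols <- cbind(a = rep(5, 8), b = rnorm(8, 10))
  rownames(vols) <- des$subject_id
  r3 <- regionwise_compare(volume_table(des, vols), "full")
  expect_equal(r3$mean_diff[r3$region_id == "a"], 0)
  expect_equal(r3$cohens_d[r3$region_id == "a"], 0)
  expect_equal(r3$p[r3$region_id == "a"], 1)
})

test_that("contrast subsetting is honoured and empty sides rejected", {
  vt <- make_vt(shift = list(treated.F = c(a = 50, b = 0, c = 0)), sd = 0.5,
                seed = 2)
  rf <- regionwise_compare(vt, "female")
  rm_ <- regionwise_compare(vt, "male")
  expect_gt(abs(rf$statistic[rf$region_id == "a"]), 5)
  expect_lt(abs(rm_$statistic[rm_$region_id == "a"]), 5)
  des_onesided <- vt$design
  des_onesided$group <- "control"
  vt2 <- volume_table(des_onesided, vt$volumes)
  expect_error(regionwise_compare(vt2, "full"), "empty contrast side")
})

test_that("area_effect_summary averages d within areas", {
  res <- data.frame(region_id = c("r1", "r2", "r3"),
                    cohens_d = c(0.5, 1.5, 0.7),
                    significant_at_q05 = c(TRUE, TRUE, FALSE))
  hier <- atlas_hierarchy(data.frame(
    region_id = c("r1", "r2", "r3"),
    area = c("white matter", "white matter", "cerebellum"),
    cluster = ""))
  s <- suppressWarnings(area_effect_summary(res, hier))
  expect_equal(s$mean_d[s$area == "white matter"], 1.0)
  expect_equal(s$n_regions[s$area == "white matter"], 2L)
  # single-region area
  s2 <- suppressWarnings(
    area_effect_summary(res, hier, region_subset = c("r1", "r3")))
  expect_equal(s2$mean_d[s2$area == "cerebellum"], 0.7)
  # empty area warned about
  expect_warning(area_effect_summary(res, hier, region_subset = "r1"),
                 "cerebellum")
  # permuting rows leaves summaries identical
  s3 <- suppressWarnings(area_effect_summary(res[3:1, ], hier))
  expect_equal(s3[order(s3$area), ], s[order(s$area), ],
               ignore_attr = TRUE)
})

test_that("dimorphism patterns follow the significance calls", {
  # deterministic cohort: every cell carries the same within-cell pattern,
  # optionally shifted in males, so significance calls are exact
  build <- function(shift_M_ctrl, shift_M_trt) {
    pattern <- c(9.7, 9.9, 10.1, 10.3)
    cells <- c(treated.M = shift_M_trt, treated.F = 0,
               control.M = shift_M_ctrl, control.F = 0)
    rows <- list(); design <- list()
    for (cell in names(cells)) {
      part <- strsplit(cell, ".", fixed = TRUE)[[1]]
      ids <- sprintf("%s_%s_%d", part[1], part[2], 1:4)
      x <- cbind(roi = pattern + cells[[cell]], other = pattern * 2)
      rownames(x) <- ids
      rows[[cell]] <- x
      design[[cell]] <- data.frame(subject_id = ids, sex = part[2],
                                   group = part[1], stringsAsFactors = FALSE)
    }
    volume_table(do.call(rbind, design), do.call(rbind, rows))
  }
  # strong control-only male excess: dimorphism lost under treatment
  d1 <- dimorphism_test(build(5, 0), "roi")
  expect_equal(d1$pattern, "dimorphism_lost")
  expect_gt(d1$control_d, 0)  # male minus female
  expect_equal(d1$treated_p, 1)
  expect_lt(d1$interaction_p, 0.05)
  # same excess in both groups: preserved, interaction exactly null
  d2 <- dimorphism_test(build(5, 5), "roi")
  expect_equal(d2$pattern, "dimorphic_preserved")
  expect_equal(d2$interaction_p, 1)
  # no sex effect anywhere
  d3 <- dimorphism_test(build(0, 0), c("roi", "other"))
  expect_equal(d3$pattern, c("not_dimorphic", "not_dimorphic"))
  # treated-only dimorphism is "other"
  d4 <- dimorphism_test(build(0, 5), "roi")
  expect_equal(d4$pattern, "other")
  expect_error(dimorphism_test(build(0, 0), "nope"), "missing")
})
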