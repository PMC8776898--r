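#' Cohen's d with pooled standard deviation
#'
#' d = (mean(x) - mean(y)) / s_p with
#' s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return The standardized mean difference (x minus y).
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("cohens_d needs at least 2 observations per sample", call. = FALSE)
  }
  sp <- pooled_sd(x, y)
  if (sp == 0) {
    stop("degenerate input: pooled standard deviation is zero", call. = FALSE)
  }
  (mean(x) - mean(y)) / sp
}

pooled_sd <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
}

#' Four-group one-way ANOVA of total brain volume
#'
#' Compares TBV across the four sex-by-treatment cells with a one-way ANOVA
#' and Tukey-adjusted pairwise comparisons of all six cell pairs.
#'
#' @param vt A `volume_table`.
#' @return List with `F`, `p`, `df` (numerator, denominator), `cell_means`,
#'   and `pairwise` (data.frame: contrast, diff, p_adj from Tukey HSD).
#' @export
compare_tbv <- function(vt) {
  stopifnot(inherits(vt, "volume_table"))
  cell <- factor(paste(vt$design$group, vt$design$sex, sep = "."))
  cnt <- table(cell)
  if (any(cnt < 2L)) {
    stop("cell(s) with fewer than 2 subjects: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "), call. = FALSE)
  }
  d <- data.frame(tbv = vt$tbv, cell = cell)
  fit <- aov(tbv ~ cell, data = d)
  a <- anova(fit)
  tk <- TukeyHSD(fit)$cell
  pairwise <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  Fv <- a[1, "F value"]
  pv <- a[1, "Pr(>F)"]
  if (a[1, "Mean Sq"] == 0) {  # identical cell means: define F = 0, p = 1
    Fv <- 0; pv <- 1
    pairwise$p_adj <- 1
  }
  list(F = Fv, p = pv, df = c(a[1, "Df"], a[2, "Df"]),
       cell_means = tapply(d$tbv, d$cell, mean), pairwise = pairwise)
}

contrast_subjects <- function(vt, contrast = c("full", "male", "female")) {
  contrast <- match.arg(contrast)
  keep <- switch(contrast,
                 full = rep(TRUE, nrow(vt$design)),
                 male = vt$design$sex == "M",
                 female = vt$design$sex == "F")
  list(treated = vt$design$subject_id[keep & vt$design$group == "treated"],
       control = vt$design$subject_id[keep & vt$design$group == "control"])
}

#' Region-wise treated-vs-control comparison with FDR
#'
#' For each atlas region, compares treated against control subjects (within
#' the full cohort or a single sex) with a two-sample test, adjusts p-values
#' across regions, and reports Cohen's d. Relative volumes divide each
#' region by the subject's total brain volume before testing.
#'
#' The sign convention is treated minus control throughout (mean difference
#' and d).
#'
#' @param vt A `volume_table`.
#' @param contrast `"full"` (both sexes), `"male"` or `"female"`.
#' @param measure `"absolute"` (mm^3) or `"relative"` (fraction of TBV).
#' @param fdr_method `"bh"` (default) or `"two_stage_bky"`.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @param level FDR level for the `significant_at_q05` call (default 0.05,
#'   strict `q < level`).
#' @return data.frame with one row per region: region_id, contrast, measure,
#'   mean_diff, statistic, df, p, q, cohens_d, significant_at_q05.
#' @export
regionwise_compare <- function(vt, contrast = c("full", "male", "female"),
                               measure = c("absolute", "relative"),
                               fdr_method = c("bh", "two_stage_bky"),
                               var_equal = FALSE, level = 0.05) {
  stopifnot(inherits(vt, "volume_table"))
  contrast <- match.arg(contrast)
  measure <- match.arg(measure)
  fdr_method <- match.arg(fdr_method)
  sets <- contrast_subjects(vt, contrast)
  if (length(sets$treated) == 0L || length(sets$control) == 0L) {
    stop("empty contrast side for contrast = ", contrast, call. = FALSE)
  }
  m <- vt$volumes
  if (measure == "relative") m <- m / vt$tbv
  res <- welch_by_column(m[sets$treated, , drop = FALSE],
                         m[sets$control, , drop = FALSE],
                         var_equal = var_equal)
  adj <- fdr_adjust(res$p, method = fdr_method, level = level)
  data.frame(region_id = vt$regions, contrast = contrast, measure = measure,
             mean_diff = res$diff, statistic = res$stat, df = res$df,
             p = res$p, q = adj$q, cohens_d = res$d,
             significant_at_q05 = adj$q < level,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorised column-wise two-sample comparison (Welch by default).
# Zero-variance columns: identical groups get stat 0, p 1, d 0; degenerate
# separated groups get p 0 with a warning.
welch_by_column <- function(x, y, var_equal = FALSE) {
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per side", call. = FALSE)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2L, var); v2 <- apply(y, 2L, var)
  diff <- m1 - m2
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  stat <- diff / se
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  d <- diff / sp
  deg <- se == 0
  if (any(deg)) {
    zerodiff <- deg & diff == 0
    stat[zerodiff] <- 0; p[zerodiff] <- 1; d[zerodiff] <- 0
    df[zerodiff] <- n1 + n2 - 2
    sep <- deg & diff != 0
    if (any(sep)) {
      warning("zero-variance column(s) with unequal means: p set to 0",
              call. = FALSE)
      p[sep] <- 0
    }
  }
  list(diff = diff, stat = stat, df = df, p = p, d = d)
}

#' Mean effect size per anatomical area
#'
#' Averages per-region Cohen's d within anatomical areas (unweighted), by
#' default over the regions flagged at the FDR level in `results`.
#'
#' @param results Output of [regionwise_compare()].
#' @param hierarchy An `atlas_hierarchy`.
#' @param region_subset Regions to aggregate; default the rows of `results`
#'   with `significant_at_q05 = TRUE`.
#' @return data.frame: area, mean_d, n_regions (areas empty after subsetting
#'   are omitted with a warning).
#' @export
area_effect_summary <- function(results, hierarchy, region_subset = NULL) {
  if (is.null(region_subset)) {
    region_subset <- results$region_id[results$significant_at_q05]
  }
  sub <- results[results$region_id %in% region_subset, , drop = FALSE]
  miss <- setdiff(region_subset, hierarchy$region_id)
  if (length(miss)) {
    stop("region(s) missing from hierarchy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  areas <- hierarchy$area[match(sub$region_id, hierarchy$region_id)]
  all_areas <- unique(hierarchy$area)
  empty <- setdiff(all_areas, areas)
  if (length(empty) && nrow(sub)) {
    warning("area(s) with no regions in subset omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!nrow(sub)) {
    return(data.frame(area = character(0), mean_d = numeric(0),
                      n_regions = integer(0), stringsAsFactors = FALSE))
  }
  agg <- tapply(sub$cohens_d, areas, mean)
  data.frame(area = names(agg), mean_d = as.numeric(agg),
             n_regions = as.integer(table(areas)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test for loss of sexual dimorphism in a-priori regions
#'
#' For each named region, tests the male-female volume difference separately
#' within controls and within the treated group (Welch, with Cohen's d signed
#' male minus female), plus the sex-by-group interaction from a two-way
#' fixed-effects linear model. The qualitative pattern follows the
#' significance calls at `alpha`:
#' `dimorphism_lost` (control significant, treated not), `dimorphic_preserved`
#' (both), `not_dimorphic` (neither), `other` (treated only). The interaction
#' p-value is reported alongside because a difference in significance is not
#' itself a test of difference.
#'
#' @param vt A `volume_table`.
#' @param regions Character vector of a-priori region ids.
#' @param alpha Significance level for the pattern calls (default 0.05).
#' @return data.frame: region_id, control_d, control_p, treated_d, treated_p,
#'   interaction_p, pattern.
#' @export
dimorphism_test <- function(vt, regions, alpha = 0.05) {
  stopifnot(inherits(vt, "volume_table"))
  miss <- setdiff(regions, vt$regions)
  if (length(miss)) {
    stop("region(s) missing from volume table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  des <- vt$design
  cnt <- table(des$sex, des$group)
  if (any(cnt < 2L)) {
    stop("need >= 2 subjects per sex within each group", call. = FALSE)
  }
  one <- function(r) {
    v <- vt$volumes[, r]
    res <- lapply(c("control", "treated"), function(g) {
      xm <- v[des$group == g & des$sex == "M"]
      xf <- v[des$group == g & des$sex == "F"]
      w <- welch_by_column(cbind(xm), cbind(xf))
      list(d = w$d, p = w$p)
    })
    fit <- lm(v ~ sex * group, data = cbind(des, v = v))
    ip <- anova(fit)["sex:group", "Pr(>F)"]
    cp <- res[[1]]$p; tp <- res[[2]]$p
    pattern <- if (cp < alpha && tp >= alpha) "dimorphism_lost"
      else if (cp < alpha && tp < alpha) "dimorphic_preserved"
      else if (cp >= alpha && tp >= alpha) "not_dimorphic"
      else "other"
    data.frame(region_id = r, control_d = res[[1]]$d, control_p = cp,
               treated_d = res[[2]]$d, treated_p = tp, interaction_p = ip,
               pattern = pattern, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(regions, one))
  rownames(out) <- NULL
  out
}
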