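#' Structural covariance matrix of one group
#'
#' Pearson correlation of absolute regional volumes across the subjects of
#' one group (inter-subject correlation of every region pair). Only regions
#' assigned to a covariance cluster are used; unassigned regions are
#' excluded. Regions with zero variance within the group cannot be
#' correlated: they are dropped with a warning and recorded in the result.
#'
#' @param vt A `volume_table`.
#' @param hierarchy An `atlas_hierarchy` covering the table's regions.
#' @param sex Optional sex filter (`"M"`/`"F"`).
#' @param group Optional group filter (`"treated"`/`"control"`).
#' @param subjects Optional explicit subject-id filter (overrides sex/group).
#' @return A `group_covariance`: list with `r` (symmetric correlation matrix,
#'   unit diagonal), `regions`, `cluster` (named cluster assignment),
#'   `n_subjects`, `label`, `dropped` (zero-variance regions).
#' @export
group_covariance <- function(vt, hierarchy, sex = NULL, group = NULL,
                             subjects = NULL) {
  stopifnot(inherits(vt, "volume_table"))
  miss <- setdiff(vt$regions, hierarchy$region_id)
  if (length(miss)) {
    stop("region(s) missing from hierarchy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  des <- vt$design
  if (is.null(subjects)) {
    keep <- rep(TRUE, nrow(des))
    if (!is.null(sex)) keep <- keep & des$sex == sex
    if (!is.null(group)) keep <- keep & des$group == group
    subjects <- des$subject_id[keep]
  }
  if (length(subjects) < 3L) {
    stop("need >= 3 subjects for a correlation matrix (got ",
         length(subjects), ")", call. = FALSE)
  }
  cl <- hierarchy$cluster[match(vt$regions, hierarchy$region_id)]
  regions <- vt$regions[!is.na(cl)]
  x <- vt$volumes[subjects, regions, drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  dropped <- regions[sds == 0]
  if (length(dropped)) {
    warning("zero-variance region(s) excluded from covariance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    regions <- setdiff(regions, dropped)
    x <- x[, regions, drop = FALSE]
  }
  r <- cor(x)
  diag(r) <- 1
  structure(list(r = r, regions = regions,
                 cluster = setNames(hierarchy$cluster[
                   match(regions, hierarchy$region_id)], regions),
                 n_subjects = length(subjects),
                 label = paste(c(group, sex), collapse = "."),
                 dropped = dropped),
            class = "group_covariance")
}

#' @export
print.group_covariance <- function(x, ...) {
  cat(sprintf("group_covariance [%s]: %d regions, n = %d subjects\n",
              x$label, length(x$regions), x$n_subjects))
  invisible(x)
}

#' Correlation values of one cluster block
#'
#' Extracts the vector of Pearson r values for one cluster pair from a group
#' covariance matrix.
#'
#' Under `convention = "paper"` the block is the full Cartesian product of
#' the two clusters: an intra-cluster block of size k contributes k^2 values
#' including the k unit self-correlations and both symmetric copies of each
#' pair; an inter-cluster block contributes |a| * |b| values. Under
#' `convention = "unique"` intra-cluster blocks contribute only the
#' k(k-1)/2 distinct off-diagonal values (inter-cluster blocks are |a| * |b|
#' either way). The Cartesian convention matches how block sample sizes are
#' commonly printed for this analysis but double-counts; entries of either
#' convention are not independent observations.
#'
#' @param cov A `group_covariance`.
#' @param cluster_a,cluster_b Cluster names (see [cluster_names()]); equal
#'   names select an intra-cluster block.
#' @param convention `"paper"` (Cartesian, default) or `"unique"`.
#' @return Numeric vector of r values.
#' @export
cluster_block_values <- function(cov, cluster_a, cluster_b = cluster_a,
                                 convention = c("paper", "unique")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cov, "group_covariance"))
  for (k in unique(c(cluster_a, cluster_b))) {
    if (!k %in% cluster_names()) {
      stop("unknown cluster name: ", k, call. = FALSE)
    }
    if (!any(cov$cluster == k)) {
      stop("cluster ", k, " has no regions in this covariance matrix",
           call. = FALSE)
    }
  }
  ia <- which(cov$cluster == cluster_a)
  ib <- which(cov$cluster == cluster_b)
  block <- cov$r[ia, ib, drop = FALSE]
  if (cluster_a == cluster_b && convention == "unique") {
    return(block[upper.tri(block)])
  }
  as.vector(block)
}

#' Mean block correlation
#'
#' Arithmetic mean of raw Pearson r values in a block. An optional Fisher-z
#' variant (mean in z space, back-transformed) is available but is not the
#' convention used for block summaries here; with Cartesian intra-cluster
#' blocks it is undefined when unit self-correlations are present.
#'
#' @param values Numeric vector of r values.
#' @param fisher Average in Fisher-z space (default FALSE).
#' @return The mean correlation.
#' @export
mean_block_correlation <- function(values, fisher = FALSE) {
  if (length(values) == 0L) stop("empty block", call. = FALSE)
  if (!fisher) return(mean(values))
  tanh(mean(atanh(values)))
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based H statistic with tie correction, chi-square p-value on k - 1
#' degrees of freedom, and the eta-squared effect size
#' eta2 = (H - k + 1) / (n - k), floored at 0. An exact permutation p-value
#' (full enumeration of group assignments) is available for small samples.
#'
#' @param groups List of >= 2 numeric vectors.
#' @param exact Compute the exact permutation p-value instead of the
#'   chi-square approximation (feasible only for small total n).
#' @return List: `H`, `p`, `eta_squared`, `df`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  k <- length(groups)
  n <- sum(sizes)
  if (n < k + 1L) stop("need total n >= number of groups + 1", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  H <- kw_statistic(x, rep.int(seq_len(k), sizes), k, n)
  p <- if (exact) {
    kw_exact_p(x, sizes, H)
  } else {
    pchisq(H, df = k - 1L, lower.tail = FALSE)
  }
  list(H = H, p = p, eta_squared = max(0, (H - k + 1) / (n - k)),
       df = k - 1L, n = n)
}

# Large-effect call: strictly greater than the threshold (0.15 is large,
# exactly 0.14 is not).
is_large_effect <- function(eta_squared, threshold = 0.14) {
  eta_squared > threshold
}

kw_statistic <- function(x, g, k, n) {
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  nj <- tabulate(g, k)
  H <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C == 0) return(0)  # all values identical
  H / C
}

# Exact p by enumerating all distinct assignments of ranks to groups.
kw_exact_p <- function(x, sizes, H_obs) {
  n <- sum(sizes)
  k <- length(sizes)
  idx <- seq_len(n)
  combs <- function(remaining, sizes) {
    if (length(sizes) == 1L) return(list(list(remaining)))
    first <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- combs(setdiff(remaining, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  asg <- combs(idx, sizes)
  hs <- vapply(asg, function(a) {
    g <- integer(n)
    for (j in seq_len(k)) g[a[[j]]] <- j
    kw_statistic(x, g, k, n)
  }, 0)
  mean(hs >= H_obs - 1e-12)
}

#' Compare cluster-block correlations across the four groups
#'
#' For each of the 21 unordered cluster pairs, extracts the block r-vector
#' from each group's covariance matrix, runs a Kruskal-Wallis test across the
#' four groups, adjusts the 21 p-values (two-stage step-up FDR by default),
#' filters on the large-effect threshold eta-squared > `eta_large`, and
#' classifies blocks passing the omnibus via post-hoc pairwise Mann-Whitney
#' tests (see [classify_effect()]).
#'
#' Block entries are correlation estimates sharing subjects, not independent
#' observations; the Cartesian convention additionally duplicates symmetric
#' pairs and (intra-cluster) includes unit self-correlations. A warning about
#' this inflation is emitted once per call under the paper convention.
#'
#' @param cov_list List of exactly 4 `group_covariance` objects (the four
#'   sex-by-treatment cells), named like `treated.M`, `treated.F`,
#'   `control.M`, `control.F` (or with labels set accordingly).
#' @param convention Block extraction convention (see
#'   [cluster_block_values()]).
#' @param fdr_method `"two_stage_bky"` (default) or `"bh"`.
#' @param level FDR level (default 0.05).
#' @param eta_large Large-effect threshold, strict inequality (default 0.14).
#' @param alpha Post-hoc pairwise significance level (default 0.05).
#' @return data.frame with one row per cluster pair: cluster_a, cluster_b,
#'   n_values (per group), mean r per group (`mean_<label>` columns), H, p,
#'   q, eta_squared, large_effect, effect_class.
#' @export
compare_blocks_across_groups <- function(cov_list,
                                         convention = c("paper", "unique"),
                                         fdr_method = c("two_stage_bky", "bh"),
                                         level = 0.05, eta_large = 0.14,
                                         alpha = 0.05) {
  convention <- match.arg(convention)
  fdr_method <- match.arg(fdr_method)
  if (length(cov_list) != 4L) {
    stop("cov_list must hold the four sex-by-treatment groups", call. = FALSE)
  }
  labels <- if (!is.null(names(cov_list))) names(cov_list) else
    vapply(cov_list, function(g) g$label, "")
  need <- c("treated.M", "treated.F", "control.M", "control.F")
  if (!setequal(labels, need)) {
    stop("cov_list must be labelled ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cov_list <- setNames(cov_list[match(need, labels)], need)
  regs <- lapply(cov_list, function(g) g$regions)
  if (!all(vapply(regs[-1], identical, TRUE, regs[[1]]))) {
    stop("region sets differ between the four groups", call. = FALSE)
  }
  if (convention == "paper") {
    warning("Cartesian block convention: entries include duplicate and ",
            "self correlations and are not independent observations",
            call. = FALSE)
  }
  cls <- cluster_names()
  pairs <- t(utils::combn(6L, 2L))
  pairs <- rbind(pairs, cbind(1:6, 1:6))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- cls[pairs[i, 1]]; b <- cls[pairs[i, 2]]
    vals <- lapply(cov_list, cluster_block_values, cluster_a = a,
                   cluster_b = b, convention = convention)
    kw <- suppressWarnings(kruskal_wallis(vals))
    means <- vapply(vals, mean, 0)
    c(list(cluster_a = a, cluster_b = b, n_values = length(vals[[1]])),
      setNames(as.list(means), paste0("mean_", names(means))),
      list(H = kw$H, p = kw$p, eta_squared = kw$eta_squared),
      list(.values = vals))
  })
  p <- vapply(rows, function(r) r$p, 0)
  adj <- fdr_adjust(p, method = fdr_method, level = level)
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[names(r) != ".values"], stringsAsFactors = FALSE)
  }))
  out$q <- adj$q
  out$large_effect <- is_large_effect(out$eta_squared, eta_large)
  out$omnibus_pass <- adj$rejected & out$large_effect
  out$effect_class <- vapply(seq_len(nrow(out)), function(i) {
    if (!out$omnibus_pass[i]) return("none")
    classify_effect(rows[[i]]$.values, alpha = alpha)$effect_class
  }, "")
  rownames(out) <- NULL
  out
}

#' Classify a block effect from post-hoc pairwise tests
#'
#' Given the four groups' block r-vectors (named `treated.M`, `treated.F`,
#' `control.M`, `control.F`), runs pairwise two-sided Mann-Whitney tests and
#' assigns: `treatment` if both treated cells differ from both control cells
#' (all four treated-vs-control tests p < alpha, all shifts in the same
#' direction) and the two treated cells do not differ; `sex_within_treated`
#' if the treated cells differ from each other (without the full treatment
#' pattern); `both` if both hold; `none` otherwise.
#'
#' @param values Named list of 4 numeric vectors.
#' @param alpha Pairwise significance level (default 0.05).
#' @return List: `effect_class` and `pairwise` (data.frame of the tests).
#' @export
classify_effect <- function(values, alpha = 0.05) {
  need <- c("treated.M", "treated.F", "control.M", "control.F")
  stopifnot(setequal(names(values), need))
  values <- values[need]
  cmb <- utils::combn(need, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(cmb, function(pr) {
    a <- values[[pr[1]]]; b <- values[[pr[2]]]
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    data.frame(a = pr[1], b = pr[2], p = wt$p.value,
               direction = sign(stats::median(a) - stats::median(b)),
               stringsAsFactors = FALSE)
  }))
  get <- function(a, b) {
    i <- which((pw$a == a & pw$b == b) | (pw$a == b & pw$b == a))
    s <- if (pw$a[i] == a) 1 else -1
    list(p = pw$p[i], dir = s * pw$direction[i])
  }
  tc <- list(get("treated.M", "control.M"), get("treated.M", "control.F"),
             get("treated.F", "control.M"), get("treated.F", "control.F"))
  trt_sig <- all(vapply(tc, function(x) x$p < alpha, TRUE))
  dirs <- vapply(tc, function(x) x$dir, 0)
  trt_pattern <- trt_sig && length(unique(dirs)) == 1L && all(dirs != 0)
  sex_sig <- get("treated.M", "treated.F")$p < alpha
  cls <- if (trt_pattern && !sex_sig) "treatment"
    else if (trt_pattern && sex_sig) "both"
    else if (sex_sig) "sex_within_treated"
    else "none"
  list(effect_class = cls, pairwise = pw)
}

#' Covariance matrices for all four sex-by-treatment cells
#'
#' Convenience wrapper computing [group_covariance()] for each cell, or for
#' the two pooled treatment groups (sexes combined) when `pooled = TRUE`.
#'
#' @param vt A `volume_table`.
#' @param hierarchy An `atlas_hierarchy`.
#' @param pooled Pool sexes within treatment (default FALSE).
#' @return Named list of `group_covariance` objects.
#' @export
covariance_by_cell <- function(vt, hierarchy, pooled = FALSE) {
  if (pooled) {
    out <- lapply(c("treated", "control"), function(g) {
      group_covariance(vt, hierarchy, group = g)
    })
    return(setNames(out, c("treated", "control")))
  }
  cells <- expand.grid(group = c("treated", "control"), sex = c("M", "F"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    group_covariance(vt, hierarchy, sex = cells$sex[i], group = cells$group[i])
  })
  setNames(out, paste(cells$group, cells$sex, sep = "."))
}
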