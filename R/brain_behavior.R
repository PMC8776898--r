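#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson r with the exact t-based two-tailed p-value:
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (pairs with a missing value in either
#'   are dropped).
#' @return List: `r`, `p`, `n` (complete pairs used).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Sex- and group-stratified brain-behavior correlation map
#'
#' Correlates each selected region's absolute volume with each behavioral
#' measure within each stratum (by default the four sex-by-treatment cells),
#' using pairwise-complete observations. P-values are two-tailed and, by
#' design, uncorrected (this is an exploratory screen); an optional BH column
#' can be added for reference.
#'
#' @param vt A `volume_table`.
#' @param behavior Behavior data.frame from [read_behavior_table()].
#' @param region_subset Regions to correlate (default: all regions in `vt`;
#'   typical use restricts to regions passing FDR in a reference contrast).
#' @param strata Named list of subject-id vectors; default the four
#'   sex-by-treatment cells.
#' @param add_bh Add a `q_bh` column (BH across all computable rows).
#' @return data.frame: region_id, measure, stratum, n, r, p, significant
#'   (p < 0.05, uncorrected), computable (FALSE when fewer than 3 complete
#'   pairs or zero variance, with r/p NA).
#' @export
brain_behavior_matrix <- function(vt, behavior, region_subset = NULL,
                                  strata = NULL, add_bh = FALSE) {
  stopifnot(inherits(vt, "volume_table"))
  if (is.null(region_subset)) region_subset <- vt$regions
  miss <- setdiff(region_subset, vt$regions)
  if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(strata)) {
    des <- vt$design
    cells <- expand.grid(group = c("treated", "control"),
                         sex = c("M", "F"), stringsAsFactors = FALSE)
    strata <- lapply(seq_len(nrow(cells)), function(i) {
      des$subject_id[des$group == cells$group[i] & des$sex == cells$sex[i]]
    })
    names(strata) <- paste(cells$group, cells$sex, sep = ".")
  }
  measures <- setdiff(names(behavior), "subject_id")
  grid <- expand.grid(region_id = region_subset, measure = measures,
                      stratum = names(strata), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    reg <- grid$region_id[i]; me <- grid$measure[i]; st <- grid$stratum[i]
    ids <- intersect(strata[[st]], behavior$subject_id)
    v <- vt$volumes[ids, reg]
    b <- behavior[[me]][match(ids, behavior$subject_id)]
    ok <- is.finite(v) & is.finite(b)
    n <- sum(ok)
    if (n < 3L || var(v[ok]) == 0 || var(b[ok]) == 0) {
      return(data.frame(region_id = reg, measure = me, stratum = st,
                        n = n, r = NA_real_, p = NA_real_,
                        significant = NA, computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    pr <- pearson_r(v[ok], b[ok])
    data.frame(region_id = reg, measure = me, stratum = st, n = pr$n,
               r = pr$r, p = pr$p, significant = pr$p < 0.05,
               computable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "correction") <- "uncorrected"
  if (add_bh) {
    out$q_bh <- NA_real_
    ok <- out$computable
    if (any(ok)) out$q_bh[ok] <- fdr_adjust(out$p[ok], "bh")$q
  }
  out
}

#' Reshape brain-behavior results to a region x (stratum:measure) r matrix
#'
#' @param results Output of [brain_behavior_matrix()].
#' @return Numeric matrix of r values (NA where not computable), regions as
#'   rows, `stratum:measure` combinations as columns.
#' @export
correlation_matrix <- function(results) {
  col <- paste(results$stratum, results$measure, sep = ":")
  regions <- unique(results$region_id)
  cols <- unique(col)
  m <- matrix(NA_real_, length(regions), length(cols),
              dimnames = list(regions, cols))
  m[cbind(match(results$region_id, regions), match(col, cols))] <- results$r
  m
}

#' Row and column ordering by average-linkage hierarchical clustering
#'
#' Orders the rows and columns of a correlation matrix independently by
#' agglomerative clustering with Euclidean distance and average (UPGMA)
#' linkage, for heatmap display. Values are used as-is (no row scaling:
#' correlations already share the \[-1, 1\] scale). Missing cells are imputed
#' as 0 for ordering only, with a flag in the result. Merging is
#' deterministic: distance ties are broken toward the earliest-created
#' clusters, so identical rows keep their input order.
#'
#' @param m Numeric matrix (e.g. from [correlation_matrix()]).
#' @return List: `row_order`, `col_order` (integer permutations), `imputed`
#'   (TRUE if any NA was zero-imputed), `row_merge`, `col_merge` (UPGMA merge
#'   traces, see [upgma()]; NULL when fewer than 2 items).
#' @export
heatmap_order <- function(m) {
  m <- as.matrix(m)
  imputed <- anyNA(m)
  if (imputed) m[is.na(m)] <- 0
  one <- function(x) {
    if (nrow(x) < 2L) {
      return(list(order = seq_len(nrow(x)), merge = NULL))
    }
    h <- upgma(dist(x))
    list(order = h$order, merge = h)
  }
  ro <- one(m)
  co <- one(t(m))
  list(row_order = ro$order, col_order = co$order, imputed = imputed,
       row_merge = ro$merge, col_merge = co$merge)
}

#' UPGMA (average linkage) agglomerative clustering
#'
#' Unweighted pair-group average-linkage clustering of a distance matrix.
#' At each step the pair of clusters with the smallest average inter-cluster
#' distance is merged; ties are broken toward the pair whose clusters were
#' created earliest (original items first, in input order), which makes the
#' result fully deterministic. Leaf order concatenates the earlier cluster's
#' leaves before the later one's.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return List: `order` (leaf permutation), `height` (merge heights),
#'   `merges` (list of length-2 member index vectors per merge), and
#'   `cophenetic` (full cophenetic distance matrix).
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  # active clusters: list of member index vectors, in creation order
  members <- as.list(seq_len(n))
  created <- seq_len(n)            # creation rank, for tie-breaks
  active <- rep(TRUE, n)
  D <- dm
  heights <- numeric(0)
  merges <- list()
  coph <- matrix(0, n, n)
  next_rank <- n
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL; bestd <- Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        if (dij < bestd - 1e-12) {
          bestd <- dij; best <- c(i, j)
        } else if (abs(dij - bestd) <= 1e-12 && !is.null(best)) {
          # tie: prefer the lexicographically smallest (creation rank) pair
          cand <- sort(created[c(i, j)]); cur <- sort(created[best])
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[which.min(created[best])]
    j <- setdiff(best, i)
    mi <- members[[i]]; mj <- members[[j]]
    coph[mi, mj] <- bestd; coph[mj, mi] <- bestd
    heights <- c(heights, bestd)
    merges <- c(merges, list(c(mi, mj)))
    # UPGMA update: unweighted average over member pairs
    ni <- length(mi); nj <- length(mj)
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (ni * D[i, k] + nj * D[j, k]) / (ni + nj)
    }
    members[[i]] <- c(mi, mj)
    active[j] <- FALSE
    next_rank <- next_rank + 1L
    created[i] <- next_rank
  }
  list(order = members[[which(active)]], height = heights, merges = merges,
       cophenetic = coph)
}
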