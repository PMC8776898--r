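# Fixture builders and independent oracles shared across test files.

# Small volume table: n subjects per cell, regions with given means (named),
# iid normal noise at sd (no correlation structure).
make_vt <- function(n_per_cell = c(treated.M = 4, treated.F = 4,
                                   control.M = 4, control.F = 4),
                    means = c(a = 10, b = 20, c = 30), sd = 1,
                    shift = NULL, seed = 1) {
  set.seed(seed)
  rows <- list()
  design <- list()
  for (cell in names(n_per_cell)) {
    part <- strsplit(cell, ".", fixed = TRUE)[[1]]
    n <- n_per_cell[[cell]]
    ids <- sprintf("%s_%s_%d", part[1], part[2], seq_len(n))
    mu <- means
    if (!is.null(shift) && cell %in% names(shift)) {
      mu <- mu + shift[[cell]]
    }
    x <- matrix(rnorm(n * length(means), mean = rep(mu, each = n), sd = sd),
                n, length(means), dimnames = list(ids, names(means)))
    rows[[cell]] <- x
    design[[cell]] <- data.frame(subject_id = ids, sex = part[2],
                                 group = part[1], stringsAsFactors = FALSE)
  }
  volume_table(do.call(rbind, design), do.call(rbind, rows))
}

write_temp_table <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext == "tsv") "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Hand-built group_covariance around an explicit correlation matrix.
make_gc <- function(r, clusters, label = "test", n_subjects = 10) {
  regions <- rownames(r)
  structure(list(r = r, regions = regions,
                 cluster = stats::setNames(clusters, regions),
                 n_subjects = n_subjects, label = label,
                 dropped = character(0)),
            class = "group_covariance")
}

# ---- independent oracles ---------------------------------------------------

# Pearson r and two-tailed p from explicit sums (no cor()/cor.test()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  dx <- x - sum(x) / n
  dy <- y - sum(y) / n
  r <- sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# Kruskal-Wallis H via the rank-ANOVA identity H = (N-1) * SSB / SST on the
# ranks (algebraically equivalent to the tie-corrected classical formula but
# an independent computation).
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  rbar <- mean(r)
  ssb <- sum(tapply(r, g, function(v) length(v) * (mean(v) - rbar)^2))
  sst <- sum((r - rbar)^2)
  if (sst == 0) return(0)
  (n - 1) * ssb / sst
}

# Brute-force UPGMA by direct agglomeration over an explicit pair-average
# distance, returning the cophenetic matrix. Independent of upgma(): clusters
# tracked as member sets, inter-cluster distance recomputed from the original
# matrix at every step.
oracle_upgma_cophenetic <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  avg_dist <- function(a, b) mean(dm[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- avg_dist(clusters[[i]], clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(j, i) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}
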