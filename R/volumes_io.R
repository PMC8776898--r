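#' Read and validate a subject-by-region volume table
#'
#' Reads a volume table (first column `subject_id`, remaining columns one
#' absolute regional volume in mm^3 per atlas region) and a design table
#' (columns `subject_id`, `sex` in \{M, F\}, `group` in \{treated, control\}),
#' joins them, validates, and computes total brain volume.
#'
#' Files may be comma- or tab-separated (detected from the header line) with
#' a header row, UTF-8, decimal point. Region column order is preserved.
#' If the volume file contains a `tbv` column it is used as the total brain
#' volume; otherwise TBV defaults to the sum of all regional volumes per
#' subject (the atlas segmentation is assumed exhaustive for this purpose).
#'
#' @param volumes_path Path to the volumes CSV/TSV.
#' @param design_path Path to the design CSV/TSV.
#' @return A `volume_table` object: a list with `design` (data.frame:
#'   subject_id, sex, group), `regions` (character), `volumes` (numeric
#'   matrix, subjects x regions, rownames = subject ids), and `tbv`
#'   (named numeric vector, mm^3).
#' @seealso [volume_table()] to build one from in-memory objects.
#' @export
read_volume_table <- function(volumes_path, design_path) {
  vols <- read_table_auto(volumes_path)
  des <- read_table_auto(design_path)
  if (names(vols)[1] != "subject_id") {
    stop("first column of the volume table must be 'subject_id'",
         call. = FALSE)
  }
  need <- c("subject_id", "sex", "group")
  if (!all(need %in% names(des))) {
    stop("design table must have columns subject_id, sex, group",
         call. = FALSE)
  }
  tbv <- NULL
  if ("tbv" %in% names(vols)) {
    tbv <- setNames(as.numeric(vols$tbv), vols$subject_id)
    vols$tbv <- NULL
  }
  regions <- setdiff(names(vols), "subject_id")
  m <- as.matrix(vols[, regions, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- vols$subject_id
  volume_table(design = des[, need], volumes = m, tbv = tbv)
}

#' Construct a validated volume table
#'
#' @param design data.frame with columns subject_id, sex (`"M"`/`"F"`),
#'   group (`"treated"`/`"control"`).
#' @param volumes Numeric matrix, subjects x regions, with rownames equal to
#'   `design$subject_id` (any order) and region ids as colnames. All entries
#'   must be finite and strictly positive (mm^3).
#' @param tbv Optional named numeric vector of per-subject total brain
#'   volume; defaults to the row sums of `volumes`.
#' @return A `volume_table` object (see [read_volume_table()]).
#' @export
volume_table <- function(design, volumes, tbv = NULL) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  rownames(design) <- NULL
  design$subject_id <- as.character(design$subject_id)
  dup <- design$subject_id[duplicated(design$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id in design: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- !design$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("unknown sex level for subject(s): ",
         paste(design$subject_id[bad_sex], " (sex=", design$sex[bad_sex], ")",
               sep = "", collapse = ", "), call. = FALSE)
  }
  bad_grp <- !design$group %in% c("treated", "control")
  if (any(bad_grp)) {
    stop("unknown group level for subject(s): ",
         paste(design$subject_id[bad_grp], " (group=", design$group[bad_grp],
               ")", sep = "", collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(volumes))) {
    stop("volume matrix must have subject ids as rownames", call. = FALSE)
  }
  miss_v <- setdiff(design$subject_id, rownames(volumes))
  miss_d <- setdiff(rownames(volumes), design$subject_id)
  if (length(miss_v) || length(miss_d)) {
    stop("subject sets differ between design and volumes",
         if (length(miss_v)) paste0("; missing volumes for: ",
                                    paste(miss_v, collapse = ", ")),
         if (length(miss_d)) paste0("; missing design for: ",
                                    paste(miss_d, collapse = ", ")),
         call. = FALSE)
  }
  volumes <- volumes[design$subject_id, , drop = FALSE]
  bad <- which(!is.finite(volumes) | volumes <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    msg <- apply(head(bad, 5L), 1L, function(ij) {
      paste0("(", rownames(volumes)[ij[1]], ", ", colnames(volumes)[ij[2]], ")")
    })
    stop("non-positive or non-numeric volume at: ",
         paste(msg, collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L),
         call. = FALSE)
  }
  if (is.null(tbv)) {
    tbv <- rowSums(volumes)
  } else {
    if (is.null(names(tbv)) || !all(design$subject_id %in% names(tbv))) {
      stop("tbv must be named by subject_id and cover all subjects",
           call. = FALSE)
    }
    tbv <- tbv[design$subject_id]
    short <- tbv < apply(volumes, 1L, max)
    if (any(short)) {
      stop("tbv smaller than the largest regional volume for: ",
           paste(design$subject_id[short], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(design = design, regions = colnames(volumes),
                 volumes = volumes, tbv = tbv),
            class = "volume_table")
}

#' @export
print.volume_table <- function(x, ...) {
  tab <- table(x$design$sex, x$design$group)
  cat(sprintf("volume_table: %d subjects x %d regions\n",
              nrow(x$volumes), length(x$regions)))
  print(tab)
  invisible(x)
}

#' Write a volume table and its design to CSV
#'
#' Inverse of [read_volume_table()]; values round-trip at full double
#' precision (17 significant digits).
#'
#' @param vt A `volume_table`.
#' @param volumes_path,design_path Output CSV paths.
#' @param tbv Write the `tbv` column explicitly (default FALSE: TBV is
#'   recomputed as the row sum on re-read).
#' @export
write_volume_table <- function(vt, volumes_path, design_path, tbv = FALSE) {
  df <- data.frame(subject_id = rownames(vt$volumes), vt$volumes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (tbv) df$tbv <- vt$tbv
  write_csv17(df, volumes_path)
  write_csv17(vt$design, design_path)
  invisible(c(volumes_path, design_path))
}

#' Read an atlas hierarchy table
#'
#' Reads a TSV/CSV with columns `region_id`, `area`, `cluster`. The cluster
#' column assigns each region to one of the six canonical structural
#' covariance clusters, or is empty for regions outside all clusters.
#'
#' @param path Path to the hierarchy table.
#' @return An `atlas_hierarchy`: a data.frame with columns `region_id`,
#'   `area`, `cluster` (NA for unassigned) and attribute `census`, the
#'   per-cluster region counts including `unassigned`.
#' @export
read_hierarchy <- function(path) {
  df <- read_table_auto(path)
  need <- c("region_id", "area", "cluster")
  if (!all(need %in% names(df))) {
    stop("hierarchy table must have columns region_id, area, cluster",
         call. = FALSE)
  }
  atlas_hierarchy(df[, need])
}

#' Canonical covariance cluster names
#'
#' The six clusters used for block-averaged structural covariance.
#' @return Character vector of the six cluster names.
#' @export
cluster_names <- function() {
  c("posterior_cortical", "hippocampal", "anterior_cortical",
    "subcortical", "midbrain", "brainstem_cerebellum")
}

#' Construct a validated atlas hierarchy
#'
#' @param df data.frame with columns region_id, area, cluster (empty string
#'   or NA for regions outside all clusters).
#' @return An `atlas_hierarchy` (see [read_hierarchy()]).
#' @export
atlas_hierarchy <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$region_id <- as.character(df$region_id)
  dup <- unique(df$region_id[duplicated(df$region_id)])
  if (length(dup)) {
    stop("region_id listed more than once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cl <- as.character(df$cluster)
  cl[is.na(cl) | cl == ""] <- NA_character_
  bad <- !is.na(cl) & !cl %in% cluster_names()
  if (any(bad)) {
    stop("unknown cluster name(s): ", paste(unique(cl[bad]), collapse = ", "),
         "; expected one of ", paste(cluster_names(), collapse = ", "),
         call. = FALSE)
  }
  df$cluster <- cl
  census <- vapply(cluster_names(), function(k) sum(cl == k, na.rm = TRUE), 0L)
  census <- c(census, unassigned = sum(is.na(cl)))
  structure(df, class = c("atlas_hierarchy", "data.frame"), census = census)
}

#' @export
print.atlas_hierarchy <- function(x, ...) {
  cat(sprintf("atlas_hierarchy: %d regions\n", nrow(x)))
  print(attr(x, "census"))
  invisible(x)
}

#' Cluster size census of a hierarchy
#'
#' @param hierarchy An `atlas_hierarchy`.
#' @return Named integer vector: regions per cluster plus `unassigned`.
#' @export
cluster_census <- function(hierarchy) {
  attr(hierarchy, "census")
}

#' Read a behavior table
#'
#' Wide CSV/TSV: one row per subject (`subject_id` column), one column per
#' behavioral measure. Missing cells are allowed (e.g. measures collected in
#' males only) and are propagated as NA; present values must be finite.
#'
#' @param path Path to the behavior table.
#' @param design Optional design data.frame; when given, behavior subject ids
#'   must be a subset of the design's.
#' @return data.frame with `subject_id` and numeric measure columns.
#' @export
read_behavior_table <- function(path, design = NULL) {
  df <- read_table_auto(path)
  if (names(df)[1] != "subject_id") {
    stop("first column of the behavior table must be 'subject_id'",
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id in behavior table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (m in setdiff(names(df), "subject_id")) {
    v <- df[[m]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite behavior value in measure ", m, call. = FALSE)
    }
  }
  if (!is.null(design)) {
    extra <- setdiff(df$subject_id, design$subject_id)
    if (length(extra)) {
      stop("behavior subjects absent from design: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Extract per-region volumes from a labeled image
#'
#' Converts voxel counts in an integer label image to absolute volumes:
#' volume(region) = (number of voxels carrying its label) x dx*dy*dz. Label 0
#' is background and is excluded. No resampling or interpolation is
#' performed; the computation is pure voxel counting.
#'
#' @param labels 3-D integer array of atlas labels.
#' @param voxel_size Numeric length-3 (dx, dy, dz) in mm, or a single number
#'   for isotropic voxels.
#' @param label_map Named numeric/integer vector or list mapping label value
#'   (names are the integer labels as strings) to region_id, e.g.
#'   `c("1" = "amygdala")`, or a data.frame with columns `label`,
#'   `region_id`.
#' @return Named numeric vector of volumes (mm^3), one entry per region in
#'   the label map. Regions absent from the image get 0 with a warning.
#' @export
extract_region_volumes <- function(labels, voxel_size, label_map) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be 3 strictly positive dimensions in mm",
         call. = FALSE)
  }
  map <- as_label_map(label_map)
  vox <- prod(voxel_size)
  lab <- as.integer(labels)
  lab <- lab[lab != 0L]
  counts <- table(lab)
  present <- as.integer(names(counts))
  unknown <- setdiff(present, map$label)
  if (length(unknown)) {
    stop("nonzero label(s) missing from label_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- setNames(numeric(nrow(map)), map$region_id)
  idx <- match(present, map$label)
  out[idx] <- as.numeric(counts) * vox
  absent <- map$region_id[!map$label %in% present]
  if (length(absent)) {
    warning("region(s) absent from the image, volume set to 0: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out
}

as_label_map <- function(label_map) {
  if (is.data.frame(label_map)) {
    if (!all(c("label", "region_id") %in% names(label_map))) {
      stop("label_map data.frame needs columns label, region_id",
           call. = FALSE)
    }
    df <- data.frame(label = as.integer(label_map$label),
                     region_id = as.character(label_map$region_id),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(label = as.integer(names(label_map)),
                     region_id = as.character(unlist(label_map, use.names = FALSE)),
                     stringsAsFactors = FALSE)
  }
  if (any(df$label == 0L)) {
    stop("label 0 is reserved for background", call. = FALSE)
  }
  if (anyDuplicated(df$label)) stop("duplicate labels in label_map",
                                    call. = FALSE)
  df
}

#' Total brain volume per subject
#'
#' Returns the per-subject total brain volume. By construction of
#' [volume_table()] this is the sum of all atlas regions unless an explicit
#' `tbv` column was supplied in the input.
#'
#' @param vt A `volume_table`.
#' @return Named numeric vector (mm^3), one entry per subject.
#' @export
total_brain_volume <- function(vt) {
  stopifnot(inherits(vt, "volume_table"))
  vt$tbv
}

# ---- plumbing -------------------------------------------------------------

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

write_csv17 <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)  # 17 significant digits: doubles round-trip
    out[is.na(x)] <- "NA"
    out
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}
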