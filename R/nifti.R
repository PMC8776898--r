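# Minimal NIfTI-1 input/output for 3-D integer label images.
#
# Only what voxel-count volume extraction needs is implemented: single-file
# .nii / .nii.gz, 3-D dims, integer (or losslessly integral float) data, no
# scaling (scl_slope 0/1, scl_inter 0), no extensions on write. Orientation
# metadata is irrelevant here because volumes are pure voxel counts.

NIFTI_HDR_SIZE <- 348L
NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE),
                 `256` = list(what = "integer", size = 1L, signed = TRUE),
                 `512` = list(what = "integer", size = 2L, signed = FALSE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3-D integer label image from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` single-file NIfTI-1 image.
#' @return A list with `labels` (3-D integer array) and `voxel_size`
#'   (numeric length 3, mm).
#' @export
read_nifti_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("missing NIfTI magic string in ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n, size, endian = endian)
  }
  dim16 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim16[1]
  if (ndim < 1L || ndim > 7L) stop("bad NIfTI dim[0]: ", ndim, call. = FALSE)
  dims <- dim16[2:(1 + max(ndim, 3L))]
  dims[dims == 0L] <- 1L
  if (prod(dims[-(1:3)]) != 1) {
    stop("only 3-D label images are supported", call. = FALSE)
  }
  dims <- dims[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype,
                        call. = FALSE)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  if (!(scl_slope %in% c(0, 1)) || scl_inter != 0) {
    stop("scaled NIfTI intensities are not supported for label images",
         call. = FALSE)
  }
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) != n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (dt$what == "double") {
    if (any(data != round(data))) {
      stop("non-integer voxel values: not a label image", call. = FALSE)
    }
    data <- as.integer(round(data))
  }
  # pixdim is stored as float32; round to its 7 significant decimal digits so
  # that decimal voxel sizes (e.g. 0.04 mm) round-trip exactly as doubles
  list(labels = array(data, dim = dims),
       voxel_size = signif(as.numeric(pixdim[2:4]), 7))
}

#' Write a 3-D integer label image to a NIfTI-1 file
#'
#' Writes a single-file little-endian NIfTI-1 image with int32 data and no
#' scaling, suitable for lossless label round-trips.
#'
#' @param labels 3-D integer array (label 0 = background).
#' @param voxel_size Numeric length-3 (dx, dy, dz) in mm, or one number for
#'   isotropic voxels.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti_labels <- function(labels, voxel_size, path) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array",
                                      call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  storage.mode(labels) <- "integer"
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                       # unused through dim_info
  w(as.integer(c(3L, dim(labels), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  writeBin(raw(14L), con)                       # intent_p1..3, intent_code
  w(8L, 2L)                                     # datatype = DT_INT32
  w(32L, 2L)                                    # bitpix
  w(0L, 2L)                                     # slice_start
  w(c(1, voxel_size, 1, 1, 1, 1), 4L)           # pixdim[8]
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  writeBin(raw(224L), con)                      # through intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                        # extension flag
  w(as.vector(labels), 4L)
  invisible(path)
}
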