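# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
# Only what a CT pipeline needs: 3-D grids, dtypes uint8/int16/int32/float32/
# float64, scl_slope/inter, sform (preferred) or qform or pixdim affine,
# byte-swapped files. The 0-based voxel->world convention of NIfTI matches
# ct_volume's.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Read a 3-D volume from a NIfTI-1 file
#'
#' The affine is taken from the sform when present, else the qform, else the
#' pixdim diagonal. `scl_slope`/`scl_inter` are applied. Space/units tags
#' written by [write_volume()] are recovered from the description field;
#' otherwise units default to Hounsfield.
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a [ct_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("unreadable file: truncated header", call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("unreadable file: not NIfTI-1", call. = FALSE)
  }
  rb <- function(off, what, n, size) # off is 0-based byte offset
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unreadable file: bad magic", call. = FALSE)
  dim0 <- rb(40L, "integer", 8L, 2L)
  ndim <- dim0[1]
  d <- dim0[2:8]
  if (ndim < 3L || any(d[seq_len(ndim)][-(1:3)] > 1L))
    stop("non-3-D data: file has dim ", paste(d[seq_len(max(ndim, 1))], collapse = "x"),
         call. = FALSE)
  d3 <- pmax(d[1:3], 1L)
  datatype <- rb(70L, "integer", 1L, 2L)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- rb(76L, "double", 8L, 4L)
  vox_offset <- rb(108L, "double", 1L, 4L)
  scl_slope <- rb(112L, "double", 1L, 4L)
  scl_inter <- rb(116L, "double", 1L, 4L)
  descrip <- rawToChar(hdr_raw[149:228])
  descrip <- sub("\\x00.*$", "", descrip, useBytes = TRUE)
  qform_code <- rb(252L, "integer", 1L, 2L)
  sform_code <- rb(254L, "integer", 1L, 2L)
  quat <- rb(256L, "double", 6L, 4L)      # b, c, d, qoffset x/y/z
  srow <- matrix(rb(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)

  A <- diag(4)
  if (sform_code > 0L) {
    A[1:3, ] <- srow
  } else if (qform_code > 0L) {
    b <- quat[1]; cq <- quat[2]; dq <- quat[3]
    a2 <- 1 - b^2 - cq^2 - dq^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - cq^2 - dq^2, 2 * (b * cq - a * dq),   2 * (b * dq + a * cq),
      2 * (b * cq + a * dq),   a^2 + cq^2 - b^2 - dq^2, 2 * (cq * dq - a * b),
      2 * (b * dq - a * cq),   2 * (cq * dq + a * b),   a^2 + dq^2 - b^2 - cq^2),
      nrow = 3L, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    A[1:3, 1:3] <- R %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    A[1:3, 4] <- quat[4:6]
  } else {
    A[1:3, 1:3] <- diag(pixdim[2:4])
  }
  if (abs(det(A)) < 1e-12) stop("singular affine", call. = FALSE)

  # skip to the data
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(d3)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < nvox) stop("unreadable file: truncated data", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), dim = d3)

  space <- if (grepl("space=template", descrip)) "template" else "native"
  units <- if (grepl("units=scaled", descrip)) "scaled" else "hounsfield"
  ct_volume(arr, A, space = space, units = units)
}

#' Write a 3-D volume to a NIfTI-1 file
#'
#' Integer-valued grids within the int16 range (e.g. Hounsfield volumes,
#' ternary lesion maps) are stored as signed 16-bit integers (bit-exact round
#' trip); anything else as 32-bit float. The affine is written as the sform
#' (code 2); space and units tags go into the description field.
#'
#' @param vol a [ct_volume()]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_ct_volume(vol))
  if (!dir.exists(dirname(path)))
    stop("unwritable path: directory does not exist: ", dirname(path), call. = FALSE)
  x <- vol$data
  int_ok <- all(is.finite(x)) && max(abs(x)) <= 32767 &&
    isTRUE(all(x == round(x)))
  datatype <- if (int_ok) 4L else 16L
  bitpix <- if (int_ok) 16L else 32L
  d <- dim(x)

  hdr <- raw(348L)
  put <- function(hdr, off, values, what, size) {
    b <- writeBin(if (what == "integer") as.integer(values) else as.numeric(values),
                  raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 39L, 0L, "integer", 1L)
  hdr <- put(hdr, 40L, c(3L, d, 1L, 1L, 1L, 1L), "integer", 2L)   # dim
  hdr <- put(hdr, 70L, datatype, "integer", 2L)
  hdr <- put(hdr, 72L, bitpix, "integer", 2L)
  vs <- voxel_size(vol)
  hdr <- put(hdr, 76L, c(1, vs, 1, 1, 1, 1), "double", 4L)        # pixdim
  hdr <- put(hdr, 108L, 352, "double", 4L)                        # vox_offset
  hdr <- put(hdr, 112L, c(1, 0), "double", 4L)                    # scl
  desc <- sprintf("ctlesion space=%s units=%s", vol$space, vol$units)
  db <- charToRaw(substr(desc, 1L, 79L))
  hdr[149L:(148L + length(db))] <- db
  hdr <- put(hdr, 252L, c(0L, 2L), "integer", 2L)                 # qform, sform
  hdr <- put(hdr, 280L, t(vol$affine[1:3, , drop = FALSE]), "double", 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                                          # no extensions
  if (int_ok) {
    writeBin(as.integer(x), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}
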