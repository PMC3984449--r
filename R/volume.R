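#' 3-D CT volume container
#'
#' A `ct_volume` holds a 3-D scalar grid together with a 4x4 affine that maps
#' 0-based voxel indices `(i, j, k)` to world coordinates in millimetres
#' (RAS+ by convention), a space tag and a units tag.
#'
#' @param data numeric 3-D array of intensities. Hounsfield units run from
#'   -1000 (air) to about 1000 (dense bone).
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world mm.
#' @param space `"native"` or `"template"`.
#' @param units `"hounsfield"` or `"scaled"` (after the invertible intensity
#'   transform, see [transform_intensity()]).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, affine, space = c("native", "template"),
                      units = c("hounsfield", "scaled")) {
  space <- match.arg(space)
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3-D data: 'data' must be a 3-D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix", call. = FALSE)
  if (!all(is.finite(affine)) || abs(det(affine)) < 1e-12)
    stop("singular affine", call. = FALSE)
  if (units == "hounsfield") {
    rng <- range(data[is.finite(data)])
    if (rng[1] < -1000 - 1e-6 || rng[2] > 1000 + 1e-6)
      warning("hounsfield intensities outside [-1000, 1000]", call. = FALSE)
  }
  structure(list(data = data, affine = affine, space = space, units = units),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  space: %s, units: %s, range: [%.4g, %.4g]\n",
              x$space, x$units, min(x$data), max(x$data)))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Voxel size in mm per axis (column norms of the affine rotation block).
#' @param vol a `ct_volume` or 4x4 affine.
#' @return numeric length-3 vector of mm.
#' @export
voxel_size <- function(vol) {
  A <- if (is_ct_volume(vol)) vol$affine else vol
  sqrt(colSums(A[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world mm
#' @param vol `ct_volume` (or 4x4 affine)
#' @param ijk n x 3 matrix of 0-based voxel indices
#' @return n x 3 matrix of world coordinates (mm)
#' @export
vox_to_world <- function(vol, ijk) {
  A <- if (is_ct_volume(vol)) vol$affine else vol
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(ijk %*% t(A[1:3, 1:3]), 2L, A[1:3, 4L], "+")
}

#' Map world mm to 0-based voxel indices (continuous)
#' @inheritParams vox_to_world
#' @param xyz n x 3 matrix of world coordinates (mm)
#' @export
world_to_vox <- function(vol, xyz) {
  A <- if (is_ct_volume(vol)) vol$affine else vol
  Ai <- solve(A)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(xyz %*% t(Ai[1:3, 1:3]), 2L, Ai[1:3, 4L], "+")
}

#' World coordinates of every voxel of a grid
#' @param vol `ct_volume`
#' @return (prod(dim)) x 3 matrix, voxels in array (column-major) order
#' @export
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  vox_to_world(vol, ijk)
}

#' Do two volumes share a grid?
#'
#' TRUE iff the array shapes are equal and the affines agree within `tol`
#' (absolute, per element).
#' @param a,b `ct_volume` objects
#' @param tol absolute per-element tolerance on the affines
#' @export
same_grid <- function(a, b, tol = 1e-5) {
  isTRUE(all(dim(a$data) == dim(b$data))) &&
    all(abs(a$affine - b$affine) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Bounding box in world mm
#' @param min_mm,max_mm length-3 numeric, componentwise min < max
#' @export
bounding_box <- function(min_mm, max_mm) {
  min_mm <- as.numeric(min_mm); max_mm <- as.numeric(max_mm)
  stopifnot(length(min_mm) == 3L, length(max_mm) == 3L)
  if (!all(min_mm < max_mm))
    stop("bounding box: min_mm must be < max_mm componentwise", call. = FALSE)
  structure(list(min_mm = min_mm, max_mm = max_mm), class = "bounding_box")
}

#' The analysis bounding box covering cortex and cerebellum
#'
#' MNI-XYZ min = (-90, -126, -82), max = (90, 90, 108).
#' @export
default_bounding_box <- function() {
  bounding_box(c(-90, -126, -82), c(90, 90, 108))
}

#' Grid geometry for a bounding box at a given isotropic resolution
#'
#' The box is inclusive at both ends: the number of samples per axis is
#' `ceiling((max - min) / res) + 1`, and the affine places voxel (0,0,0) at
#' `min_mm` with `res`-mm spacing, axis-aligned RAS.
#' @param box a [bounding_box()]
#' @param resolution_mm isotropic voxel size, mm (> 0)
#' @return list with `dim` (integer 3-vector) and `affine` (4x4)
#' @export
grid_for_box <- function(box, resolution_mm) {
  if (resolution_mm <= 0) stop("resolution must be > 0", call. = FALSE)
  n <- as.integer(ceiling((box$max_mm - box$min_mm) / resolution_mm - 1e-9)) + 1L
  A <- diag(c(rep(resolution_mm, 3), 1))
  A[1:3, 4] <- box$min_mm
  list(dim = n, affine = A)
}

#' Orthogonal-slice display of a volume
#' @param x `ct_volume`
#' @param k slice index (1-based, 3rd axis); default middle
#' @param ... passed to [graphics::image()]
#' @export
plot.ct_volume <- function(x, k = NULL, ...) {
  d <- dim(x$data)
  if (is.null(k)) k <- (d[3] + 1L) %/% 2L
  graphics::image(x$data[, , k], col = grDevices::gray.colors(128),
                  asp = d[2] / d[1], axes = FALSE,
                  main = sprintf("axial slice k = %d", k), ...)
  invisible(x)
}
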