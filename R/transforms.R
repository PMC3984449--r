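# Resampling and spatial transforms.
#
# Sampling ("pull-back") convention: every registration step is stored as the
# map taking world coordinates of the FIXED (output) grid to world coordinates
# of the MOVING (input) volume, so warping is a single interpolation
#   out(x) = in(step_map(x)).
# A pipeline chain (rigid, affine, deformable) therefore composes as
#   native_position = S_rigid %*% S_affine %*% (x + d(x)).

#' Sample a volume at arbitrary world coordinates
#'
#' @param vol `ct_volume`
#' @param xyz n x 3 matrix of world mm coordinates
#' @param method `"linear"` (trilinear) or `"nearest"`
#' @param background value for points outside the grid
#' @return numeric vector of length n
#' @export
resample_points <- function(vol, xyz, method = c("linear", "nearest"),
                            background = 0) {
  method <- match.arg(method)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  n <- nrow(xyz)
  out <- rep.int(as.numeric(background), n)
  chunk <- 2000000L
  d <- dim(vol$data)
  arr <- vol$data
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- world_to_vox(vol, xyz[s:e, , drop = FALSE])
    if (method == "nearest") {
      i <- round(p[, 1]); j <- round(p[, 2]); k <- round(p[, 3])
      ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
      idx <- 1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
      v <- out[s:e]; v[ok] <- arr[idx]; out[s:e] <- v
    } else {
      eps <- 1e-6
      ok <- p[, 1] >= -eps & p[, 1] <= d[1] - 1 + eps &
            p[, 2] >= -eps & p[, 2] <= d[2] - 1 + eps &
            p[, 3] >= -eps & p[, 3] <= d[3] - 1 + eps
      if (any(ok)) {
        x <- pmin(pmax(p[ok, 1], 0), d[1] - 1)
        y <- pmin(pmax(p[ok, 2], 0), d[2] - 1)
        z <- pmin(pmax(p[ok, 3], 0), d[3] - 1)
        i0 <- pmin(floor(x), d[1] - 2); fx <- x - i0
        j0 <- pmin(floor(y), d[2] - 2); fy <- y - j0
        k0 <- pmin(floor(z), d[3] - 2); fz <- z - k0
        at <- function(i, j, k) arr[1 + i + d[1] * (j + d[2] * k)]
        val <-
          at(i0,     j0,     k0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
          at(i0 + 1, j0,     k0    ) * fx       * (1 - fy) * (1 - fz) +
          at(i0,     j0 + 1, k0    ) * (1 - fx) * fy       * (1 - fz) +
          at(i0 + 1, j0 + 1, k0    ) * fx       * fy       * (1 - fz) +
          at(i0,     j0,     k0 + 1) * (1 - fx) * (1 - fy) * fz +
          at(i0 + 1, j0,     k0 + 1) * fx       * (1 - fy) * fz +
          at(i0,     j0 + 1, k0 + 1) * (1 - fx) * fy       * fz +
          at(i0 + 1, j0 + 1, k0 + 1) * fx       * fy       * fz
        v <- out[s:e]; v[ok] <- val; out[s:e] <- v
      }
    }
  }
  out
}

#' Resample a volume onto a target grid through an optional sampling map
#'
#' @param vol moving `ct_volume`
#' @param target `ct_volume` (its grid is used) or a list with `dim`/`affine`
#'   as from [grid_for_box()]
#' @param map `NULL` (identity), a 4x4 matrix, or a function taking and
#'   returning an n x 3 matrix of world coordinates (target world -> moving
#'   world)
#' @param method,background see [resample_points()]
#' @param space,units tags for the output volume (default: moving volume's)
#' @return `ct_volume` on the target grid
#' @export
resample_to_grid <- function(vol, target, map = NULL,
                             method = "linear", background = 0,
                             space = vol$space, units = vol$units) {
  if (is_ct_volume(target)) {
    tdim <- dim(target$data); taff <- target$affine
  } else {
    tdim <- target$dim; taff <- target$affine
  }
  tmp <- ct_volume(array(0, tdim), taff, space = "native", units = "scaled")
  xyz <- grid_world_coords(tmp)
  if (!is.null(map)) {
    xyz <- if (is.matrix(map))
      sweep(xyz %*% t(map[1:3, 1:3]), 2L, map[1:3, 4L], "+")
    else map(xyz)
  }
  vals <- resample_points(vol, xyz, method = method, background = background)
  out <- ct_volume(array(vals, tdim), taff, space = space,
                   units = if (units == "hounsfield") "hounsfield" else "scaled")
  out
}

# --- spatial transform steps -------------------------------------------------

#' Affine transform step
#'
#' `matrix` is the sampling map: fixed-grid world mm -> moving-volume world mm.
#' @param matrix 4x4
#' @param provenance step name, e.g. "rigid" or "affine"
#' @export
spatial_transform_affine <- function(matrix, provenance = "affine") {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4L, 4L)), abs(det(matrix)) > 1e-12)
  structure(list(kind = "affine", matrix = matrix, provenance = provenance),
            class = "spatial_transform")
}

#' Dense displacement step
#'
#' Displacement d(x) in mm defined on a template grid; the sampling map is
#' x -> x + d(x).
#' @param disp list of three 3-D arrays (dx, dy, dz) in mm
#' @param grid_affine 4x4 affine of the grid the field lives on
#' @param provenance step name
#' @export
spatial_transform_displacement <- function(disp, grid_affine,
                                           provenance = "deformable") {
  stopifnot(length(disp) == 3L)
  structure(list(kind = "displacement", disp = disp,
                 grid_affine = as.matrix(grid_affine),
                 dim = dim(disp[[1]]), provenance = provenance),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform: %s (%s)>\n", x$kind, x$provenance))
  invisible(x)
}

disp_as_volume <- function(st, comp) {
  ct_volume(st$disp[[comp]], st$grid_affine, space = "template", units = "scaled")
}

# sample a displacement step at world points; zero outside its grid
sample_displacement <- function(st, xyz) {
  cbind(resample_points(disp_as_volume(st, 1L), xyz),
        resample_points(disp_as_volume(st, 2L), xyz),
        resample_points(disp_as_volume(st, 3L), xyz))
}

step_map <- function(st, xyz) {
  if (st$kind == "affine")
    sweep(xyz %*% t(st$matrix[1:3, 1:3]), 2L, st$matrix[1:3, 4L], "+")
  else
    xyz + sample_displacement(st, xyz)
}

#' Composite sampling map of a pipeline chain
#'
#' `chain` is a list of `spatial_transform` steps in PIPELINE order (the order
#' they were applied to the data, e.g. rigid, affine, deformable). Returns a
#' function mapping template-grid world coordinates to native world
#' coordinates, i.e. the single interpolation map that reproduces the whole
#' cascade of resamplings.
#' @param chain list of [spatial_transform_affine()] /
#'   [spatial_transform_displacement()] steps
#' @export
chain_sampling_map <- function(chain) {
  force(chain)
  function(xyz) {
    for (st in rev(chain)) xyz <- step_map(st, xyz)
    xyz
  }
}

#' Warp a native-space volume to a template grid with a transform chain
#' @param vol native `ct_volume`
#' @param chain list of transform steps in pipeline order
#' @param target template grid (`ct_volume` or `grid_for_box()` list)
#' @param method,background see [resample_points()]
#' @export
warp_with_chain <- function(vol, chain, target, method = "linear",
                            background = 0) {
  resample_to_grid(vol, target, map = chain_sampling_map(chain),
                   method = method, background = background,
                   space = "template", units = vol$units)
}

# --- displacement utilities --------------------------------------------------

#' Invert a dense displacement field by fixed-point iteration
#'
#' Solves v(x) = -d(x + v(x)) so that (id + v) is the inverse of (id + d);
#' 20 iterations or 0.05 mm max-update tolerance.
#' @param st displacement `spatial_transform`
#' @param max_iter,tol_mm iteration controls
#' @param stride compute the inverse on every `stride`-th grid sample (the
#'   field is smooth; a coarser inverse grid is cheaper and interpolates to
#'   the same answer within the tolerance)
#' @return displacement `spatial_transform` (on the strided grid)
#' @export
invert_displacement <- function(st, max_iter = 20L, tol_mm = 0.05,
                                stride = 1L) {
  stopifnot(st$kind == "displacement")
  A <- st$grid_affine
  d <- st$dim
  if (stride > 1L) {
    idx <- lapply(1:3, function(a) seq(1L, d[a], by = stride))
    A[1:3, 1:3] <- A[1:3, 1:3] * stride
    d <- vapply(idx, length, integer(1))
  }
  g <- ct_volume(array(0, d), A, space = "template", units = "scaled")
  xyz <- grid_world_coords(g)
  v <- matrix(0, nrow(xyz), 3L)
  for (it in seq_len(max_iter)) {
    dv <- sample_displacement(st, xyz + v)
    vnew <- -dv
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol_mm) break
  }
  disp <- lapply(1:3, function(a) array(v[, a], d))
  spatial_transform_displacement(disp, A,
                                 provenance = paste0("inverse-", st$provenance))
}

#' Jacobian determinant of the mapping x -> x + d(x)
#'
#' Central differences on the field's grid; values <= 0 indicate folding.
#' @param st displacement `spatial_transform`
#' @return 3-D array of determinants
#' @export
jacobian_determinant <- function(st) {
  stopifnot(st$kind == "displacement")
  vs <- voxel_size(st$grid_affine)
  d <- st$dim
  grad <- function(arr, axis) {
    # central differences along axis, one-sided at the ends, in mm^-1
    n <- d[axis]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    den <- (ip - im) * vs[axis]
    if (axis == 1L) (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) / den
    else if (axis == 2L) sweep(arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE], 2L, den, "/")
    else sweep(arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE], 3L, den, "/")
  }
  J <- vector("list", 9L)
  for (r in 1:3) for (c in 1:3)
    J[[(r - 1) * 3 + c]] <- grad(st$disp[[r]], c) + as.numeric(r == c)
  J11 <- J[[1]]; J12 <- J[[2]]; J13 <- J[[3]]
  J21 <- J[[4]]; J22 <- J[[5]]; J23 <- J[[6]]
  J31 <- J[[7]]; J32 <- J[[8]]; J33 <- J[[9]]
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  array(det, d)
}
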