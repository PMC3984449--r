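# Intensity-based registration: 6-parameter rigid and 12-parameter affine
# fits with a multi-resolution schedule and a choice of similarity metric
# (normalized cross-correlation, default, or normalized mutual information),
# plus a demons-style multi-resolution deformable registration with Gaussian
# (fluid + elastic) regularization.

rot3 <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Build a 4x4 affine from registration parameters
#'
#' Rigid: `p = (tx, ty, tz, rx, ry, rz)` (mm, radians). Affine adds
#' log-scales `(s1, s2, s3)` and shears `(h1, h2, h3)`. Rotation/scale/shear
#' act about `center` (world mm).
#' @param p parameter vector (6 or 12)
#' @param center length-3 world centre of rotation
#' @export
params_to_affine <- function(p, center = c(0, 0, 0)) {
  np <- length(p)
  stopifnot(np %in% c(6L, 12L))
  L <- rot3(p[4:6])
  if (np == 12L) {
    S <- diag(exp(p[7:9]))
    H <- diag(3); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    L <- L %*% H %*% S
  }
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- p[1:3] + center - L %*% center
  M
}

metric_ncc <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

metric_nmi <- function(a, b, nbins = 32L, ra = range(a), rb = range(b)) {
  ia <- pmin(pmax(floor((a - ra[1]) / (diff(ra) + 1e-12) * nbins), 0), nbins - 1)
  ib <- pmin(pmax(floor((b - rb[1]) / (diff(rb) + 1e-12) * nbins), 0), nbins - 1)
  h <- tabulate(1L + ia + nbins * ib, nbins * nbins)
  p <- h / sum(h)
  px <- rowSums(matrix(p, nbins)); py <- colSums(matrix(p, nbins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hxy <- ent(p)
  if (hxy < 1e-12) return(2)
  (ent(px) + ent(py)) / hxy
}

strided_points <- function(vol, stride, min_value = NULL, jitter = FALSE) {
  d <- dim(vol$data)
  ii <- seq(1L, d[1], by = stride)
  jj <- seq(1L, d[2], by = stride)
  kk <- seq(1L, d[3], by = stride)
  ijk <- cbind(
    rep.int(ii - 1L, length(jj) * length(kk)),
    rep.int(rep(jj - 1L, each = length(ii)), length(kk)),
    rep(kk - 1L, each = length(ii) * length(jj)))
  vals <- as.numeric(vol$data[ii, jj, kk])
  if (!is.null(min_value)) {
    # keep the informative (head) region plus a margin shell around it, so
    # the head/air boundary still contributes to the similarity
    keep <- vals > min_value
    box_lo <- pmax(apply(ijk[keep, , drop = FALSE], 2L, min) - 3L * stride, 0L)
    box_hi <- apply(ijk[keep, , drop = FALSE], 2L, max) + 3L * stride
    keep <- ijk[, 1] >= box_lo[1] & ijk[, 1] <= box_hi[1] &
            ijk[, 2] >= box_lo[2] & ijk[, 2] <= box_hi[2] &
            ijk[, 3] >= box_lo[3] & ijk[, 3] <= box_hi[3]
    ijk <- ijk[keep, , drop = FALSE]
    vals <- vals[keep]
  }
  if (jitter && stride > 1L) {
    # deterministic sub-voxel offsets de-alias the regular sampling lattice,
    # whose interpolation ripple otherwise biases the optimum by ~0.5 voxel;
    # fixed values are re-interpolated at the shifted positions. Points that
    # land within half a voxel of the grid boundary are dropped, NOT clamped:
    # clamped points sit exactly on the in-field edge and make the objective
    # discontinuous at the identity, stalling the optimizer.
    n <- nrow(ijk)
    phi <- (sqrt(5) - 1) / 2
    off <- cbind(((seq_len(n) * phi) %% 1) - 0.5,
                 ((seq_len(n) * phi^2) %% 1) - 0.5,
                 ((seq_len(n) * phi^3) %% 1) - 0.5) * (stride / 2)
    ijk <- ijk + off
    core <- ijk[, 1] >= 0.5 & ijk[, 1] <= d[1] - 1.5 &
            ijk[, 2] >= 0.5 & ijk[, 2] <= d[2] - 1.5 &
            ijk[, 3] >= 0.5 & ijk[, 3] <= d[3] - 1.5
    ijk <- ijk[core, , drop = FALSE]
    xyz <- vox_to_world(vol, ijk)
    return(list(xyz = xyz, vals = resample_points(vol, xyz)))
  }
  list(xyz = vox_to_world(vol, ijk), vals = vals)
}

#' Rigid or 12-parameter affine registration
#'
#' Finds the sampling map M (fixed world -> moving world) that maximizes the
#' similarity between `moving(M x)` and `fixed(x)`, by quasi-Newton
#' optimization over a coarse-to-fine subsampling schedule.
#'
#' @param moving,fixed `ct_volume`s in comparable units
#' @param kind `"rigid"` (6 parameters) or `"affine"` (12)
#' @param metric `"ncc"` or `"nmi"`
#' @param background out-of-grid value for the moving volume
#' @param init optional starting parameter vector
#' @param strides integer subsampling factors, coarse to fine; default chosen
#'   from the grid size
#' @param maxit iterations per level
#' @return list: `matrix` (4x4 sampling map), `par`, `similarity_before`,
#'   `similarity_after`, `convergence`
#' @export
register_affine <- function(moving, fixed, kind = c("rigid", "affine"),
                            metric = c("ncc", "nmi"), background = 0,
                            init = NULL, strides = NULL,
                            maxit = c(40L, 15L)) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  np <- if (kind == "rigid") 6L else 12L
  d <- dim(fixed$data)
  if (is.null(strides)) {
    s1 <- max(1L, ceiling((prod(d) / 15000)^(1 / 3)))
    s2 <- max(1L, ceiling(s1 / 2))
    strides <- unique(c(s1, s2))
  }
  maxit <- rep_len(maxit, length(strides))
  center <- as.numeric(vox_to_world(fixed, matrix((d - 1) / 2, 1)))
  par <- if (is.null(init)) rep(0, np) else init
  parscale <- c(rep(2, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))[1:np]

  sim_fun <- if (metric == "ncc") metric_ncc else function(a, b)
    metric_nmi(a, b, ra = range(fixed$data), rb = range(moving$data))

  conv <- NA_integer_
  minv <- background + 0.02 * diff(range(fixed$data))
  # the similarity is computed over in-field samples only and weighted by
  # the overlap fraction: otherwise the moving volume's field-of-view edge
  # (constant background fill) acts as fake structure that a degenerate
  # "registration" can align with the head boundary
  mk_fn <- function(lev) function(p) {
    M <- params_to_affine(p, center)
    xm <- sweep(lev$xyz %*% t(M[1:3, 1:3]), 2L, M[1:3, 4L], "+")
    mv <- resample_points(moving, xm, background = NA_real_)
    ok <- !is.na(mv)
    frac <- mean(ok)
    if (frac < 0.25) return(1)
    -sim_fun(mv[ok], lev$vals[ok]) * min(1, frac / 0.5)
  }
  for (li in seq_along(strides)) {
    fn <- mk_fn(strided_points(fixed, strides[li], min_value = minv,
                               jitter = TRUE))
    op <- stats::optim(par, fn, method = "BFGS",
                       control = list(maxit = maxit[li], parscale = parscale,
                                      reltol = 1e-7))
    par <- op$par
    conv <- op$convergence
  }
  # report before/after similarity honestly, on the full (unsubsampled) grid
  # -- the subsampled objective can be optimistically overfit
  fn_full <- mk_fn(strided_points(fixed, 1L, min_value = minv))
  sim_before <- -fn_full(rep(0, np))
  sim_after <- -fn_full(par)
  list(matrix = params_to_affine(par, center), par = par,
       similarity_before = sim_before, similarity_after = sim_after,
       convergence = conv)
}

# --- deformable (demons) -----------------------------------------------------

downsample_volume <- function(vol, stride) {
  if (stride <= 1L) return(vol)
  sm <- smooth_array(vol$data, rep(0.45 * stride, 3))
  d <- dim(vol$data)
  ii <- seq(1L, d[1], by = stride)
  jj <- seq(1L, d[2], by = stride)
  kk <- seq(1L, d[3], by = stride)
  A <- vol$affine
  A[1:3, 1:3] <- A[1:3, 1:3] * stride
  v <- ct_volume(sm[ii, jj, kk, drop = FALSE], A, space = vol$space,
                 units = "scaled")
  v$units <- vol$units
  v
}

grad_mm <- function(arr, vs) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    den <- (ip - im) * vs[ax]
    g[[ax]] <- if (ax == 1L) (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) / den
    else if (ax == 2L) sweep(arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE], 2L, den, "/")
    else sweep(arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE], 3L, den, "/")
  }
  g
}

#' Demons-style deformable registration
#'
#' Multi-resolution demons (Thirion): at each level the update force is
#' `r * grad(f) / (|grad(f)|^2 + (r/kappa)^2)` with r = fixed - warped
#' moving and the fixed-image gradient, which bounds update steps at
#' kappa/2 mm; updates are smoothed with a fluid kernel and the accumulated
#' field with a light elastic kernel. Returns the displacement d(x) in mm on
#' the finest level grid; the sampling map is x -> x + d(x).
#'
#' @param moving,fixed `ct_volume`s on the same grid
#' @param background out-of-grid value for `moving`
#' @param levels integer strides, coarse to fine
#' @param iters iterations per level
#' @param sigma_fluid_vox,sigma_elastic_vox regularization, in level voxels
#' @param kappa_mm demons step bound (default: the finest voxel size)
#' @return a displacement [spatial_transform_displacement()]
#' @export
register_demons <- function(moving, fixed, background = 0,
                            levels = c(4L, 2L, 1L), iters = c(30L, 40L, 25L),
                            sigma_fluid_vox = 2, sigma_elastic_vox = 0.5,
                            kappa_mm = NULL) {
  stop_if_grid_mismatch(moving, fixed, "registration inputs")
  iters <- rep_len(iters, length(levels))
  if (is.null(kappa_mm)) kappa_mm <- mean(voxel_size(fixed))
  u <- NULL        # n x 3 displacement at current level
  prev_st <- NULL
  for (li in seq_along(levels)) {
    s <- levels[li]
    fx <- downsample_volume(fixed, s)
    mv <- downsample_volume(moving, s)
    d <- dim(fx$data)
    vs <- voxel_size(fx)
    xyz <- grid_world_coords(fx)
    u <- if (is.null(prev_st)) matrix(0, nrow(xyz), 3L)
         else sample_displacement(prev_st, xyz)
    f <- as.numeric(fx$data)
    g <- grad_mm(fx$data, vs)
    g1 <- as.numeric(g[[1]]); g2c <- as.numeric(g[[2]]); g3 <- as.numeric(g[[3]])
    gg <- g1^2 + g2c^2 + g3^2
    # confine the field to the (feathered) support of the fixed image: there
    # is no matching information outside it, and an extrapolated field would
    # disturb structures (skull) the affine step already aligned
    supp <- (fx$data > background + 0.02 * diff(range(fx$data))) |
            (mv$data > background + 0.02 * diff(range(mv$data)))
    wsupp <- pmin(1, 1.5 * as.numeric(smooth_array(supp + 0, rep(2, 3))))
    for (it in seq_len(iters[li])) {
      w <- resample_points(mv, xyz + u, background = background)
      r <- f - w
      den <- gg + (r / kappa_mm)^2
      den[den < 1e-9] <- Inf
      fac <- r / den
      upd <- cbind(fac * g1, fac * g2c, fac * g3)
      for (a in 1:3)
        upd[, a] <- as.numeric(smooth_array(array(upd[, a], d),
                                            rep(sigma_fluid_vox, 3)))
      u <- u + upd
      if (sigma_elastic_vox > 0)
        for (a in 1:3)
          u[, a] <- as.numeric(smooth_array(array(u[, a], d),
                                            rep(sigma_elastic_vox, 3)))
    }
    u <- u * wsupp
    prev_st <- spatial_transform_displacement(
      lapply(1:3, function(a) array(u[, a], d)), fx$affine, "deformable")
  }
  prev_st
}
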