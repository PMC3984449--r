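# Preprocessing: non-head removal, invertible contrast-enhancing intensity
# transform, rigid coregistration to the template.

#' Largest 26-connected component of a logical 3-D mask
#'
#' Frontier-vectorized flood fill; used by [strip_nonhead()] and the cluster
#' filter. Exported mainly for testing.
#' @param mask logical 3-D array
#' @return logical array: the largest component (ties: first found)
#' @export
largest_component <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  loffs <- offs[, 1] + dp[1] * offs[, 2] + dp[1] * dp[2] * offs[, 3]
  unvisited <- which(pad)
  visited <- logical(length(pad))
  best <- integer(0)
  for (seed in unvisited) {
    if (visited[seed]) next
    comp <- integer(0)
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nb <- unique(as.vector(outer(frontier, loffs, "+")))
      nb <- nb[pad[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- array(FALSE, dp)
  out[best] <- TRUE
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

#' Remove neck/side/noise signal outside the head
#'
#' Threshold-based clustering at a fraction of the maximum intensity: voxels
#' with shifted intensity (HU + 1000, so air is 0) at or above
#' `frac * max(shifted)` are clustered by 26-connectivity and only the largest
#' component (the head) is kept; everything else is set to -1000.
#'
#' @param vol `ct_volume` in Hounsfield units
#' @param frac threshold fraction of the maximum shifted intensity (0.001,
#'   i.e. 0.1 percent)
#' @return `ct_volume` with non-head voxels at -1000
#' @export
strip_nonhead <- function(vol, frac = 0.001) {
  stopifnot(is_ct_volume(vol))
  if (vol$units != "hounsfield")
    stop("strip_nonhead expects hounsfield units", call. = FALSE)
  shifted <- vol$data + 1000
  thr <- frac * max(shifted)
  mask <- shifted >= thr & shifted > 0
  if (!any(mask)) stop("no head found", call. = FALSE)
  keep <- largest_component(mask)
  out <- vol$data
  out[!keep] <- -1000
  ct_volume(out, vol$affine, space = vol$space, units = "hounsfield")
}

#' Piecewise invertible intensity transform specification
#'
#' Forward map (Hounsfield -> scaled):
#' \itemize{
#'   \item i in \[-1000, -100\]: t(i) = i + 1000   (outputs 0..900)
#'   \item i in (-100, 100\]:    t(i) = 911 + (i + 99) * 11   (outputs (900, 3100\])
#'   \item i > 100:             t(i) = i + 3000
#' }
#' The middle slope (3100 - 911) / 199 is exactly 11, so the map is continuous
#' and strictly increasing; integer HU round-trip exactly. The open interval
#' (-100, -99) is covered by extending the middle line, so interpolated
#' (non-integer) intensities invert exactly too; scaled outputs in (900, 911)
#' belong to that extension.
#' @return list with the printed breakpoints, class `intensity_transform_spec`
#' @export
intensity_transform_spec <- function() {
  structure(list(
    segments = data.frame(
      input_lo = c(-1000, -100, 100),
      input_hi = c(-100, 100, Inf),
      slope = c(1, (3100 - 911) / 199, 1),
      offset = c(1000, 911 + 99 * (3100 - 911) / 199, 3000))),
    class = "intensity_transform_spec")
}

#' @export
print.intensity_transform_spec <- function(x, ...) {
  cat("<intensity_transform_spec> piecewise linear HU -> scaled:\n")
  print(x$segments)
  invisible(x)
}

ih_forward <- function(i) {
  ifelse(i <= -100, i + 1000,
         ifelse(i <= 100, 911 + (i + 99) * 11, i + 3000))
}

ih_inverse <- function(o) {
  ifelse(o <= 900, o - 1000,
         ifelse(o <= 3100, (o - 911) / 11 - 99, o - 3000))
}

#' Apply the invertible intensity transform (or its inverse)
#'
#' Direction is inferred from the units tag: Hounsfield volumes are mapped
#' forward to scaled units, scaled volumes are mapped back to Hounsfield.
#' @param vol `ct_volume`
#' @param spec an [intensity_transform_spec()] (the printed map; kept as an
#'   argument for provenance)
#' @param direction `"auto"`, `"forward"` or `"inverse"`
#' @return `ct_volume` with flipped units
#' @export
transform_intensity <- function(vol, spec = intensity_transform_spec(),
                                direction = c("auto", "forward", "inverse")) {
  direction <- match.arg(direction)
  if (!all(is.finite(vol$data)))
    stop("non-finite intensities", call. = FALSE)
  if (direction == "auto")
    direction <- if (vol$units == "hounsfield") "forward" else "inverse"
  if (direction == "forward") {
    if (vol$units != "hounsfield")
      stop("forward transform expects hounsfield units", call. = FALSE)
    out <- ih_forward(vol$data)
    units <- "scaled"
  } else {
    if (vol$units != "scaled")
      stop("inverse transform expects scaled units", call. = FALSE)
    out <- ih_inverse(vol$data)
    units <- "hounsfield"
  }
  v <- ct_volume(array(out, dim(vol$data)), vol$affine, space = vol$space,
                 units = "scaled")
  v$units <- units
  v
}

#' Rigidly coregister a head CT to the template
#'
#' Estimates a 6-parameter rigid-body transform maximizing an intensity
#' similarity (normalized cross-correlation by default, normalized mutual
#' information optionally) over a multi-resolution schedule, then resamples
#' the scan onto the template grid.
#'
#' @param vol `ct_volume` (native space)
#' @param template template `ct_volume` (defines the output grid); same units
#'   as `vol`
#' @param metric `"ncc"` or `"nmi"`
#' @return list with `volume` (resampled on the template grid), `transform`
#'   (a [spatial_transform_affine()]: template world -> native world) and
#'   `similarity` (before/after)
#' @export
coregister_rigid <- function(vol, template, metric = c("ncc", "nmi")) {
  metric <- match.arg(metric)
  if (vol$units != template$units)
    stop("coregister_rigid: units of scan and template differ", call. = FALSE)
  bg <- if (vol$units == "hounsfield") -1000 else 0
  fit <- register_affine(vol, template, kind = "rigid", metric = metric,
                         background = bg, maxit = c(60L, 25L))
  if (fit$similarity_after < 0.2)
    warning("rigid registration: very low final similarity (",
            signif(fit$similarity_after, 3), "); possible failure", call. = FALSE)
  out <- resample_to_grid(vol, template, map = fit$matrix, background = bg,
                          space = "template", units = vol$units)
  list(volume = out,
       transform = spatial_transform_affine(fit$matrix, "rigid"),
       similarity = c(before = fit$similarity_before,
                      after = fit$similarity_after))
}
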