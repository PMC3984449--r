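# Normative voxelwise model from control scans and the Crawford-Howell
# single-case t statistic:
#   t = (x - mean_c) / (sd_c * sqrt((n + 1) / n)),   df = n - 1
# where mean_c and sd_c are the voxelwise sample mean and sample SD of the n
# controls and x is the patient value. Thresholding the t map two-tailed
# yields a ternary lesion map: +1 hyper-intense (hemorrhage), -1 hypo-intense
# (ischemia), 0 otherwise.

#' Fit the voxelwise normative model from control scans
#'
#' The controls must be fully normalized, resliced and smoothed with the same
#' kernel as the patients will be (the same pipeline is used for patients and
#' controls). Mean and SD maps are the voxelwise sample mean and sample SD
#' (denominator n - 1); the brain mask keeps the voxels where every control
#' exceeds the background threshold.
#'
#' @param controls list of >= 2 `ct_volume`s on a common template grid
#' @param fwhm_mm smoothing that was applied to the controls (recorded, and
#'   required to match the patient smoothing at test time)
#' @param mask_threshold scaled-unit background cut: a voxel enters the brain
#'   mask iff all controls exceed it
#' @return object of class `control_model`: `mean_map`, `sd_map`, `n`,
#'   `brain_mask`, `degenerate` (sd = 0 voxels), `fwhm_mm`, `affine`
#' @export
control_model <- function(controls, fwhm_mm = 5, mask_threshold = 500) {
  if (length(controls) < 2L)
    stop("need at least 2 control volumes", call. = FALSE)
  ref <- controls[[1L]]
  for (v in controls[-1L]) stop_if_grid_mismatch(ref, v, "control volumes")
  d <- dim(ref$data)
  n <- length(controls)
  X <- matrix(vapply(controls, function(v) as.numeric(v$data),
                     numeric(prod(d))), nrow = prod(d))
  m <- rowMeans(X)
  sd_v <- sqrt(rowSums((X - m)^2) / (n - 1))
  brain <- rowSums(X > mask_threshold) == n
  structure(list(
    mean_map = array(m, d),
    sd_map = array(sd_v, d),
    n = n,
    brain_mask = array(brain, d),
    degenerate = array(sd_v == 0, d),
    fwhm_mm = fwhm_mm,
    affine = ref$affine),
    class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("<control_model> n = %d controls, df = %d, fwhm = %g mm\n",
              x$n, x$n - 1L, x$fwhm_mm))
  cat(sprintf("  brain mask: %d voxels (%.1f%% of grid); degenerate sd=0: %d\n",
              sum(x$brain_mask), 100 * mean(x$brain_mask),
              sum(x$degenerate & x$brain_mask)))
  invisible(x)
}

#' @export
summary.control_model <- function(object, ...) {
  bm <- object$brain_mask
  out <- list(n = object$n, df = object$n - 1L, fwhm_mm = object$fwhm_mm,
              n_brain_voxels = sum(bm),
              mean_in_brain = mean(object$mean_map[bm]),
              sd_in_brain = mean(object$sd_map[bm]))
  class(out) <- "summary.control_model"
  out
}

#' @export
print.summary.control_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Normative CT model: n = %d controls (df = %d), smoothing %g mm FWHM\n",
    "  brain mask: %d voxels\n",
    "  mean intensity in brain: %.1f (scaled units)\n",
    "  mean voxelwise SD in brain: %.2f\n"),
    x$n, x$df, x$fwhm_mm, x$n_brain_voxels, x$mean_in_brain, x$sd_in_brain))
  invisible(x)
}

#' @export
plot.control_model <- function(x, k = NULL, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  arr <- if (what == "mean") x$mean_map else x$sd_map
  d <- dim(arr)
  if (is.null(k)) k <- (d[3] + 1L) %/% 2L
  graphics::image(arr[, , k], col = grDevices::gray.colors(128),
                  asp = d[2] / d[1], axes = FALSE,
                  main = sprintf("%s map, slice %d", what, k), ...)
  invisible(x)
}

#' Crawford-Howell t map of a patient against the normative model
#'
#' t = (x - mean) / (sd * sqrt((n + 1) / n)) per voxel, df = n - 1. Voxels
#' with sd = 0 are flagged undefined (NA in the map).
#' @param patient `ct_volume`, normalized and smoothed identically to the
#'   controls
#' @param model a [control_model()]
#' @return object of class `t_score_map`: `t_map`, `df`, `undefined`,
#'   `affine`
#' @export
crawford_howell_t <- function(patient, model) {
  stopifnot(is_ct_volume(patient), inherits(model, "control_model"))
  if (!all(dim(patient$data) == dim(model$mean_map)) ||
      any(abs(patient$affine - model$affine) > 1e-5))
    stop("grid mismatch: patient is not on the model grid", call. = FALSE)
  n <- model$n
  denom <- model$sd_map * sqrt((n + 1) / n)
  t <- (patient$data - model$mean_map) / denom
  t[model$degenerate] <- NA_real_
  structure(list(t_map = t, df = n - 1L, undefined = model$degenerate,
                 affine = model$affine),
            class = "t_score_map")
}

#' predict method: Crawford-Howell t map for a new patient scan
#' @param object a [control_model()]
#' @param newdata a normalized, smoothed patient `ct_volume`
#' @param ... unused
#' @export
predict.control_model <- function(object, newdata, ...) {
  crawford_howell_t(newdata, object)
}

#' Ternary lesion map container
#' @param labels integer 3-D array with values in \{-1, 0, 1\}
#' @param affine grid affine
#' @param space `"template"` or `"native"`
#' @param alpha,correction,t_critical thresholding record
#' @export
lesion_map <- function(labels, affine, space = "template", alpha = NA_real_,
                       correction = "none", t_critical = NA_real_) {
  stopifnot(all(labels %in% c(-1L, 0L, 1L)))
  structure(list(labels = labels, affine = as.matrix(affine), space = space,
                 alpha = alpha, correction = correction,
                 t_critical = t_critical),
            class = "lesion_map")
}

#' @export
print.lesion_map <- function(x, ...) {
  cat(sprintf(
    "<lesion_map> %s space, alpha = %g (%s), t_crit = %.4g\n  -1 (ischemia): %d voxels, +1 (hemorrhage): %d voxels\n",
    x$space, x$alpha, x$correction, x$t_critical,
    sum(x$labels == -1L), sum(x$labels == 1L)))
  invisible(x)
}

#' Threshold a t-score map into a ternary lesion map
#'
#' Two-tailed Student critical value at level `alpha` with the model's df;
#' with Bonferroni correction the level is divided by the number of in-mask
#' voxels. Labels: +1 where t > t_crit (hyper-intense, hemorrhage), -1 where
#' t < -t_crit (hypo-intense, ischemia), 0 elsewhere; only inside the brain
#' mask, and undefined (sd = 0) voxels stay 0.
#'
#' @param t a [crawford_howell_t()] result
#' @param alpha significance level in (0, 1)
#' @param correction `"bonferroni"` or `"none"`
#' @param brain_mask logical array of tested voxels
#' @return a [lesion_map()] (template space)
#' @export
threshold_tmap <- function(t, alpha = 0.05,
                           correction = c("bonferroni", "none"), brain_mask) {
  correction <- match.arg(correction)
  stopifnot(inherits(t, "t_score_map"), alpha > 0, alpha < 1)
  n_mask <- sum(brain_mask)
  if (n_mask == 0L) stop("empty brain mask", call. = FALSE)
  alpha_v <- if (correction == "bonferroni") alpha / n_mask else alpha
  t_crit <- stats::qt(1 - alpha_v / 2, df = t$df)
  lab <- array(0L, dim(t$t_map))
  ok <- brain_mask & !t$undefined & !is.na(t$t_map)
  lab[ok & t$t_map > t_crit] <- 1L
  lab[ok & t$t_map < -t_crit] <- -1L
  lesion_map(lab, t$affine, space = "template", alpha = alpha,
             correction = correction, t_critical = t_crit)
}

#' Remove small clusters from a lesion map (visualization post-filter)
#'
#' Connected components (26-connectivity, per sign) smaller than
#' `min_voxels` are set to 0. Off by default in the pipeline.
#' @param map a [lesion_map()]
#' @param min_voxels minimum cluster size to keep
#' @export
filter_clusters <- function(map, min_voxels = 1400L) {
  stopifnot(inherits(map, "lesion_map"))
  lab <- map$labels
  for (sgn in c(-1L, 1L)) {
    m <- lab == sgn
    while (any(m)) {
      comp <- largest_component(m)
      if (sum(comp) < min_voxels) { lab[m] <- 0L; break }
      m <- m & !comp
    }
  }
  lesion_map(lab, map$affine, space = map$space, alpha = map$alpha,
             correction = map$correction, t_critical = map$t_critical)
}
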