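# Two-step spatial normalization to template space: 12-parameter affine, then
# deformable registration of skull-stripped images, with
# intensity-distribution-based ventricle/contour segmentation in between.

#' Pearson correlation between two volumes over a mask
#' @param a,b `ct_volume`s on the same grid
#' @param mask logical array (default: everywhere)
#' @export
spatial_correlation <- function(a, b, mask = NULL) {
  stop_if_grid_mismatch(a, b)
  if (is.null(mask)) mask <- array(TRUE, dim(a$data))
  stats::cor(a$data[mask], b$data[mask])
}

#' First normalization step: 12-parameter affine to the template
#'
#' @param vol rigidly coregistered `ct_volume` in scaled units, on the
#'   template grid
#' @param template scaled template `ct_volume`
#' @param metric similarity metric, see [register_affine()]
#' @return list: `volume` (affine-warped, on the template grid), `transform`
#'   ([spatial_transform_affine()]), `similarity` before/after
#' @export
affine_normalize <- function(vol, template, metric = "ncc") {
  fit <- register_affine(vol, template, kind = "affine", metric = metric,
                         background = 0)
  out <- resample_to_grid(vol, template, map = fit$matrix, background = 0,
                          space = "template", units = vol$units)
  list(volume = out,
       transform = spatial_transform_affine(fit$matrix, "affine"),
       similarity = c(before = fit$similarity_before,
                      after = fit$similarity_after))
}

#' Segment ventricles and brain contours from the intensity distribution
#'
#' Thresholds are mean +/- `sd_multiplier` * SD of the soft-tissue intensity
#' distribution. The in-head mask is `intensity > min_intensity`; the
#' threshold estimation additionally excludes bone
#' (`intensity > bone_intensity`), because the very bright skull otherwise
#' inflates the SD until the 2-SD rule selects nothing. The ventricle mask is
#' the in-head voxels below mean - k SD; the contour mask is the in-head
#' voxels above mean + k SD (which always includes bone).
#'
#' @param vol affine-normalized `ct_volume` in scaled units
#' @param sd_multiplier k in mean +/- k SD (default 2)
#' @param min_intensity scaled-unit floor of the in-head mask (500 ~ -500 HU)
#' @param bone_intensity scaled-unit start of bone (3400 ~ +400 HU)
#' @param estimator `"robust"` (default; median and MAD-scaled SD, which
#'   coincide with mean/SD for Gaussian intensities but are immune to the
#'   partial-volume tails created by interpolation) or `"moment"` (plain
#'   mean/SD)
#' @return `segmentation_masks` list: `ventricle_mask`, `contour_mask`,
#'   `in_head`, `threshold_low`, `threshold_high`
#' @export
segment_masks <- function(vol, sd_multiplier = 2, min_intensity = 500,
                          bone_intensity = 3400,
                          estimator = c("robust", "moment")) {
  stopifnot(is_ct_volume(vol))
  estimator <- match.arg(estimator)
  in_head <- vol$data > min_intensity
  soft <- in_head & vol$data <= bone_intensity
  if (!any(soft)) stop("segment_masks: empty in-head mask", call. = FALSE)
  vals <- vol$data[soft]
  if (estimator == "robust") {
    m <- stats::median(vals); s <- stats::mad(vals)
  } else {
    m <- mean(vals); s <- stats::sd(vals)
  }
  if (!is.finite(s) || s < 1e-9)
    stop("degenerate intensity distribution (SD = 0)", call. = FALSE)
  lo <- m - sd_multiplier * s
  hi <- m + sd_multiplier * s
  structure(list(
    ventricle_mask = in_head & vol$data < lo,
    contour_mask = in_head & vol$data > hi,
    in_head = in_head,
    threshold_low = lo, threshold_high = hi),
    class = "segmentation_masks")
}

#' Remove skull, contours and CSF from a volume
#'
#' Voxels in the ventricle or contour mask, and everything outside the
#' in-head mask, are set to the background value (0 in scaled units); all
#' other voxels are unchanged. Lesioned voxels are NOT excluded.
#' @param vol `ct_volume` (scaled units)
#' @param masks a [segment_masks()] result on the same grid
#' @param background replacement value
#' @return skull-stripped `ct_volume`
#' @export
skull_strip <- function(vol, masks, background = 0) {
  if (!all(dim(vol$data) == dim(masks$in_head)))
    stop("grid mismatch: masks were computed on a different grid", call. = FALSE)
  out <- vol$data
  drop <- !masks$in_head | masks$ventricle_mask | masks$contour_mask
  out[drop] <- background
  v <- ct_volume(out, vol$affine, space = vol$space, units = "scaled")
  v$units <- vol$units
  v
}

#' Second normalization step: deformable registration of skull-stripped pairs
#'
#' A smooth deformation is estimated from the skull-stripped scaled image to
#' the skull-stripped scaled template and applied to the unmasked (carrier)
#' image. Warns if the deformation folds (Jacobian determinant <= 0
#' anywhere on the carrier grid).
#'
#' @param stripped skull-stripped patient image (template grid)
#' @param stripped_template skull-stripped template (same grid)
#' @param carrier the unmasked affine-normalized image the deformation is
#'   applied to
#' @param ... passed to [register_demons()]
#' @return list: `volume` (warped carrier), `transform` (displacement step)
#' @export
nonlinear_normalize <- function(stripped, stripped_template, carrier, ...) {
  stop_if_grid_mismatch(stripped, stripped_template, "stripped pair")
  stop_if_grid_mismatch(stripped, carrier, "stripped image and carrier")
  st <- register_demons(stripped, stripped_template, background = 0, ...)
  jd <- jacobian_determinant(st)
  if (any(jd <= 0))
    warning(sprintf("deformation folds at %.3f%% of voxels",
                    100 * mean(jd <= 0)), call. = FALSE)
  out <- resample_to_grid(carrier, carrier,
                          map = function(xyz) xyz + sample_displacement(st, xyz),
                          background = 0, space = "template",
                          units = carrier$units)
  list(volume = out, transform = st)
}

#' Reslice a template-space volume onto a bounding-box grid
#'
#' The output grid spans the box inclusively at `resolution_mm` (number of
#' samples per axis: ceiling((max - min) / res) + 1); trilinear interpolation,
#' out-of-field voxels get the background value.
#' @param vol `ct_volume`, space = template
#' @param box a [bounding_box()]
#' @param resolution_mm isotropic output resolution (> 0)
#' @param background out-of-field value (default by units: -1000 HU, else 0)
#' @export
reslice <- function(vol, box = default_bounding_box(), resolution_mm = 1,
                    background = NULL) {
  if (vol$space != "template")
    stop("reslice expects a template-space volume", call. = FALSE)
  if (resolution_mm <= 0) stop("resolution must be > 0", call. = FALSE)
  if (is.null(background))
    background <- if (vol$units == "hounsfield") -1000 else 0
  g <- grid_for_box(box, resolution_mm)
  resample_to_grid(vol, g, background = background, space = "template",
                   units = vol$units)
}

#' Inverse-warp a ternary lesion map to native space
#'
#' Inverts the whole transform chain (affine parts exactly, displacement
#' parts by fixed-point iteration) and resamples the map onto the native
#' reference grid with nearest-neighbour interpolation, so labels stay in
#' \{-1, 0, 1\}.
#' @param map `lesion_map` (template space)
#' @param chain list of transform steps in pipeline order (e.g. rigid,
#'   affine, deformable)
#' @param native_ref `ct_volume` whose grid defines the output
#' @return `lesion_map` in native space
#' @export
inverse_warp <- function(map, chain, native_ref) {
  stopifnot(inherits(map, "lesion_map"))
  inv_steps <- lapply(chain, function(st) {
    if (st$kind == "affine") list(kind = "affine", matrix = solve(st$matrix))
    else list(kind = "displacement",
              st = invert_displacement(st, stride = 2L))
  })
  psi <- function(xyz) {
    for (s in inv_steps) {
      xyz <- if (s$kind == "affine")
        sweep(xyz %*% t(s$matrix[1:3, 1:3]), 2L, s$matrix[1:3, 4L], "+")
      else xyz + sample_displacement(s$st, xyz)
    }
    xyz
  }
  vol <- ct_volume(map$labels + 0, map$affine, space = "template", units = "scaled")
  out <- resample_to_grid(vol, native_ref, map = psi, method = "nearest",
                          background = 0)
  lesion_map(array(as.integer(out$data), dim(out$data)), native_ref$affine,
             space = "native", alpha = map$alpha, correction = map$correction,
             t_critical = map$t_critical)
}

#' Full spatial normalization of a native CT to the template grid
#'
#' Runs the preprocessing and two-step normalization cascade:
#' strip_nonhead -> rigid coregistration -> intensity transform -> affine
#' normalization -> ventricle/contour segmentation + skull strip ->
#' deformable registration -> reslice -> Gaussian smoothing. Stage-wise
#' spatial correlations with the scaled template are recorded.
#'
#' @param vol native `ct_volume` in Hounsfield units
#' @param template template `ct_volume` in Hounsfield units on the analysis
#'   grid
#' @param config a [pipeline_config()]
#' @param template_cache optionally, a precomputed [prepare_template()]
#'   result (recommended when normalizing many scans)
#' @return list: `normalized` (smoothed, scaled, template grid),
#'   `unsmoothed`, `chain` (rigid, affine, deformable steps),
#'   `correlations` (named: coregistered, affine, deformable), `masks`
#' @export
normalize_to_template <- function(vol, template, config = pipeline_config(),
                                  template_cache = NULL) {
  tc <- if (is.null(template_cache)) prepare_template(template, config)
        else template_cache
  # stage correlations are measured on smoothed images (the scale at which
  # the statistical comparison operates); unsmoothed voxelwise correlation is
  # dominated by sub-voxel jitter of the thin skull ring
  stage_cor <- function(v)
    spatial_correlation(smooth_volume(v, config$fwhm_mm),
                        tc$template_smoothed, tc$head_mask)
  stripped_head <- strip_nonhead(vol, frac = config$head_threshold_frac)
  rig <- coregister_rigid(stripped_head, tc$template_hu, metric = config$metric)
  scal <- transform_intensity(rig$volume)
  corr_coreg <- stage_cor(scal)
  aff <- affine_normalize(scal, tc$template_scaled, metric = config$metric)
  # re-resample the affine stage in ONE interpolation from the native scan
  # (rigid and affine sampling maps compose), halving partial-volume blur
  aff_vol <- resample_to_grid(stripped_head, tc$template_hu,
                              map = rig$transform$matrix %*% aff$transform$matrix,
                              background = -1000, space = "template",
                              units = "hounsfield")
  aff_vol <- transform_intensity(aff_vol)
  corr_affine <- stage_cor(aff_vol)
  masks <- segment_masks(aff_vol, sd_multiplier = config$sd_multiplier,
                         min_intensity = config$head_min_scaled,
                         bone_intensity = config$bone_min_scaled)
  strip <- skull_strip(aff_vol, masks)
  nl <- nonlinear_normalize(strip, tc$stripped_template, aff_vol)
  corr_nl <- stage_cor(nl$volume)
  res <- reslice(nl$volume, config$bounding_box, config$resolution_mm)
  sm <- smooth_volume(res, config$fwhm_mm)
  list(normalized = sm, unsmoothed = res,
       chain = list(rig$transform, aff$transform, nl$transform),
       correlations = c(coregistered = corr_coreg, affine = corr_affine,
                        deformable = corr_nl),
       masks = masks)
}

#' Precompute the template-side inputs of the normalization cascade
#'
#' Reslices the template onto the analysis grid if needed, builds its scaled
#' version, its segmentation masks and its skull-stripped scaled version
#' (template and patients are processed identically).
#' @inheritParams normalize_to_template
#' @export
prepare_template <- function(template, config = pipeline_config()) {
  g <- grid_for_box(config$bounding_box, config$resolution_mm)
  gv <- ct_volume(array(0, g$dim), g$affine, space = "template", units = "scaled")
  if (!same_grid(template, gv)) {
    template <- resample_to_grid(template, gv, background = -1000,
                                 space = "template", units = template$units)
  }
  template$space <- "template"
  ts <- transform_intensity(template)
  masks <- segment_masks(ts, sd_multiplier = config$sd_multiplier,
                         min_intensity = config$head_min_scaled,
                         bone_intensity = config$bone_min_scaled)
  list(template_hu = template,
       template_scaled = ts,
       template_smoothed = smooth_volume(ts, config$fwhm_mm),
       masks = masks,
       head_mask = masks$in_head,
       stripped_template = skull_strip(ts, masks))
}
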