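#' Frozen pipeline configuration
#'
#' Defaults reproduce the selected operating point of the method: 5 mm FWHM
#' smoothing, p < 0.05 Bonferroni-corrected thresholding, 1 mm reslicing over
#' the cortex+cerebellum bounding box, mean +/- 2 SD segmentation, head
#' threshold at 0.1 percent of maximum intensity, VLSM with a 10/10 coverage
#' rule and 1000 permutations at p < 0.01.
#'
#' @param fwhm_mm Gaussian smoothing FWHM, mm
#' @param alpha significance level for lesion thresholding
#' @param correction `"bonferroni"` or `"none"`
#' @param resolution_mm isotropic reslicing resolution, mm
#' @param bounding_box a [bounding_box()]
#' @param sd_multiplier k of the mean +/- k SD segmentation rule
#' @param head_threshold_frac head-extraction threshold (fraction of max
#'   shifted intensity)
#' @param head_min_scaled in-head floor in scaled units (brain mask /
#'   segmentation)
#' @param bone_min_scaled scaled intensity above which voxels count as bone
#' @param metric registration similarity metric, `"ncc"` or `"nmi"`
#' @param vlsm_min_group,vlsm_n_perm,vlsm_alpha VLSM defaults
#' @param seed seed for any stochastic stage
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(fwhm_mm = 5, alpha = 0.05,
                            correction = "bonferroni", resolution_mm = 1,
                            bounding_box = default_bounding_box(),
                            sd_multiplier = 2, head_threshold_frac = 0.001,
                            head_min_scaled = 500, bone_min_scaled = 3400,
                            metric = "ncc",
                            vlsm_min_group = 10L, vlsm_n_perm = 1000L,
                            vlsm_alpha = 0.01, seed = 1L) {
  stopifnot(fwhm_mm > 0, alpha > 0, alpha < 1, resolution_mm > 0,
            sd_multiplier > 0, head_threshold_frac > 0)
  structure(list(fwhm_mm = fwhm_mm, alpha = alpha, correction = correction,
                 resolution_mm = resolution_mm, bounding_box = bounding_box,
                 sd_multiplier = sd_multiplier,
                 head_threshold_frac = head_threshold_frac,
                 head_min_scaled = head_min_scaled,
                 bone_min_scaled = bone_min_scaled, metric = metric,
                 vlsm_min_group = vlsm_min_group, vlsm_n_perm = vlsm_n_perm,
                 vlsm_alpha = vlsm_alpha, seed = seed),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  smoothing %g mm FWHM, alpha %g (%s), reslice %g mm\n",
              x$fwhm_mm, x$alpha, x$correction, x$resolution_mm))
  cat(sprintf("  box [%s; %s], seg mean+/-%g SD, head thr %g, metric %s\n",
              paste(x$bounding_box$min_mm, collapse = " "),
              paste(x$bounding_box$max_mm, collapse = " "),
              x$sd_multiplier, x$head_threshold_frac, x$metric))
  invisible(x)
}

#' End-to-end automated lesion delineation for one patient scan
#'
#' Runs the full cascade: head extraction, rigid coregistration, intensity
#' transform, affine normalization, segmentation-guided skull stripping,
#' deformable normalization, reslicing, smoothing, Crawford-Howell t map
#' against the control model, ternary thresholding, and inverse warping of
#' the lesion map back to the native grid.
#'
#' @param patient_native native-space `ct_volume` in Hounsfield units
#' @param template template `ct_volume` (Hounsfield units)
#' @param model a [control_model()] built with the same config
#' @param config a [pipeline_config()]
#' @param template_cache optional [prepare_template()] result
#' @return object of class `delineation`: `template_map` and `native_map`
#'   ([lesion_map()]s), `t_map` ([crawford_howell_t()] result), `normalized`
#'   patient volume, transform `chain`, stage `correlations`, and a
#'   `provenance` list echoing the configuration
#' @export
delineate <- function(patient_native, template, model,
                      config = pipeline_config(), template_cache = NULL) {
  stopifnot(inherits(model, "control_model"))
  if (abs(model$fwhm_mm - config$fwhm_mm) > 1e-9)
    stop("control model smoothing (", model$fwhm_mm,
         " mm) does not match config fwhm (", config$fwhm_mm, " mm)",
         call. = FALSE)
  norm <- normalize_to_template(patient_native, template, config,
                                template_cache = template_cache)
  tmap <- crawford_howell_t(norm$normalized, model)
  lm_template <- threshold_tmap(tmap, alpha = config$alpha,
                                correction = config$correction,
                                brain_mask = model$brain_mask)
  lm_native <- inverse_warp(lm_template, norm$chain, patient_native)
  structure(list(
    template_map = lm_template,
    native_map = lm_native,
    t_map = tmap,
    normalized = norm$normalized,
    chain = norm$chain,
    correlations = norm$correlations,
    provenance = list(config = unclass(config), n_controls = model$n)),
    class = "delineation")
}

#' @export
print.delineation <- function(x, ...) {
  cat("<delineation>\n  template-space map: ")
  print(x$template_map)
  cat(sprintf("  stage correlations: coreg %.3f -> affine %.3f -> deformable %.3f\n",
              x$correlations[["coregistered"]], x$correlations[["affine"]],
              x$correlations[["deformable"]]))
  invisible(x)
}
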