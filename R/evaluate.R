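# Segmentation scoring: confusion counts, Dice similarity index
# DSI = 2|X n Y| / (|X| + |Y|), sensitivity TP/(TP+FN), positive predictive
# value TP/(TP+FP), and parameter sweeps over smoothing / significance.

as_binary_mask <- function(x) {
  if (inherits(x, "lesion_map")) return(x$labels != 0L)
  if (is_ct_volume(x)) return(x$data != 0)
  if (is.logical(x)) return(x)
  x != 0
}

#' Voxelwise confusion counts of an estimated vs a reference mask
#'
#' Ternary lesion maps are binarized (|label| > 0) first.
#' @param estimate,reference binary arrays or [lesion_map()]s on one grid
#' @param evaluation_mask optional logical array restricting the evaluation
#' @return list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`
#' @export
confusion_counts <- function(estimate, reference, evaluation_mask = NULL) {
  e <- as_binary_mask(estimate)
  r <- as_binary_mask(reference)
  if (!all(dim(e) == dim(r)))
    stop("grid mismatch: estimate and reference differ in shape", call. = FALSE)
  if (is.null(evaluation_mask)) evaluation_mask <- array(TRUE, dim(e))
  e <- e[evaluation_mask]; r <- r[evaluation_mask]
  structure(list(tp = sum(e & r), fp = sum(e & !r),
                 tn = sum(!e & !r), fn = sum(!e & r)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Dice similarity index
#'
#' DSI = 2 |X n Y| / (|X| + |Y|): 1 for perfect overlap, 0 for disjoint
#' masks. If both masks are empty the DSI is defined as 1 (perfect agreement
#' on absence) and flagged with attribute `both_empty`.
#' @param estimate,reference binary arrays or [lesion_map()]s
#' @export
dsi <- function(estimate, reference) {
  e <- as_binary_mask(estimate)
  r <- as_binary_mask(reference)
  if (!all(dim(e) == dim(r)))
    stop("grid mismatch", call. = FALSE)
  denom <- sum(e) + sum(r)
  if (denom == 0L) return(structure(1, both_empty = TRUE))
  2 * sum(e & r) / denom
}

#' Sensitivity and positive predictive value from confusion counts
#'
#' sensitivity = TP / (TP + FN), PPV = TP / (TP + FP). A zero denominator
#' yields NA flagged with an attribute, never a silent 0.
#' @param counts a [confusion_counts()]
#' @return named numeric: `sensitivity`, `ppv` (possibly NA with attributes)
#' @export
sensitivity_ppv <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
          else NA_real_
  ppv <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp)
         else NA_real_
  out <- c(sensitivity = sens, ppv = ppv)
  if (is.na(sens)) attr(out, "sensitivity_undefined") <- TRUE
  if (is.na(ppv)) attr(out, "ppv_undefined") <- TRUE
  out
}

#' DSI from confusion counts (the printed identity)
#'
#' 2 TP / ((FP + TP) + (TP + FN)); equals [dsi()] on the same masks.
#' @param counts a [confusion_counts()]
#' @export
dsi_from_counts <- function(counts) {
  denom <- (counts$fp + counts$tp) + (counts$tp + counts$fn)
  if (denom == 0L) return(structure(1, both_empty = TRUE))
  2 * counts$tp / denom
}

#' Sweep smoothing and significance settings over simulated cases
#'
#' Each case is spatially normalized once (normalization does not depend on
#' the statistical settings); then, for every smoothing level, the controls
#' and the case are re-smoothed, the control model is re-built, and the
#' ternary map is computed for every significance setting. DSI, sensitivity
#' and PPV are evaluated in template space against the forward-warped ground
#' truth mask.
#'
#' @param cases list from [generate_simulation_grid()]
#' @param controls_unsmoothed list of normalized but UNsmoothed control
#'   volumes (template grid)
#' @param template template `ct_volume`
#' @param config base [pipeline_config()]
#' @param fwhm_list smoothing levels to test, mm
#' @param alpha_list significance levels
#' @param corrections character vector of corrections to test
#' @return data.frame: case_id, radius, delta, fwhm, alpha, correction, dsi,
#'   sensitivity, ppv, tp, fp, tn, fn; attribute `best` holds the
#'   configuration (fwhm, alpha, correction) maximizing mean DSI
#' @export
parameter_sweep <- function(cases, controls_unsmoothed, template,
                            config = pipeline_config(),
                            fwhm_list = c(5), alpha_list = c(0.05),
                            corrections = "bonferroni") {
  tc <- prepare_template(template, config)
  norm_cases <- lapply(cases, function(cs)
    normalize_to_template(cs$volume, template, config, template_cache = tc))
  rows <- list()
  for (fw in fwhm_list) {
    ctrl_sm <- lapply(controls_unsmoothed, smooth_volume, fwhm_mm = fw)
    model <- control_model(ctrl_sm, fwhm_mm = fw,
                           mask_threshold = config$head_min_scaled)
    for (ci in seq_along(cases)) {
      nc <- norm_cases[[ci]]
      pat <- smooth_volume(nc$unsmoothed, fw)
      tmap <- crawford_howell_t(pat, model)
      truth_vol <- ct_volume(cases[[ci]]$mask + 0, cases[[ci]]$volume$affine,
                             space = "native", units = "scaled")
      truth <- warp_with_chain(truth_vol, nc$chain, pat, method = "nearest")
      tr <- truth$data > 0
      for (al in alpha_list) for (corr in corrections) {
        lm <- threshold_tmap(tmap, alpha = al, correction = corr,
                             brain_mask = model$brain_mask)
        cc <- confusion_counts(lm, tr, model$brain_mask)
        sp <- sensitivity_ppv(cc)
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = cases[[ci]]$case_id,
          radius = cases[[ci]]$spec$radius_mm,
          delta = cases[[ci]]$spec$delta_pct,
          fwhm = fw, alpha = al, correction = corr,
          dsi = dsi(lm$labels != 0L, tr),
          sensitivity = sp[["sensitivity"]], ppv = sp[["ppv"]],
          tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(dsi ~ fwhm + alpha + correction, data = out, FUN = mean)
  attr(out, "best") <- agg[which.max(agg$dsi), , drop = FALSE]
  out
}
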