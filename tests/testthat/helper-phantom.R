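# Shared synthetic-world fixtures, built lazily and cached for the whole run.
#
# Two worlds are used:
#  * a 6 mm "toy" world for cheap operation contracts;
#  * the 3 mm "reduced" world (same bounding box as the 1 mm analysis grid,
#    20-subject control cohort) for the registration-heavy end-to-end checks.
# The paper-scale 1 mm / 72-control world is not run in the test suite for
# runtime reasons; the 3 mm world keeps every pipeline stage and contrast
# identical and only coarsens the grid.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

fx_spec6 <- function() phantom_spec(resolution_mm = 6)
fx_phantom6 <- function() fx_get("ph6", function() make_phantom_template(fx_spec6()))
fx_scaled6 <- function() fx_get("ps6", function() transform_intensity(fx_phantom6()))

fx_spec3 <- function() phantom_spec(resolution_mm = 3)
fx_phantom3 <- function() fx_get("ph3", function() make_phantom_template(fx_spec3()))
fx_config3 <- function() pipeline_config(resolution_mm = 3)
fx_template_cache3 <- function()
  fx_get("tc3", function() prepare_template(fx_phantom3(), fx_config3()))

# 20-subject cohort of the 3 mm world, fully normalized; the expensive shared
# fixture behind the end-to-end acceptance checks
fx_cohort_norms3 <- function() fx_get("norms3", function() {
  ph <- fx_phantom3(); cfg <- fx_config3(); tc <- fx_template_cache3()
  cohort <- make_control_cohort(ph, 20L, seed = 100L, spec = fx_spec3())
  lapply(cohort, function(v)
    normalize_to_template(v, ph, cfg, template_cache = tc))
})

fx_model3 <- function() fx_get("model3", function() {
  cfg <- fx_config3()
  control_model(lapply(fx_cohort_norms3(), `[[`, "normalized"),
                fwhm_mm = cfg$fwhm_mm, mask_threshold = cfg$head_min_scaled)
})

# a patient scan from the same generator (distinct seed, not in the cohort)
fx_patient3 <- function() fx_get("pat3", function()
  simulate_subject(fx_phantom3(), seed = 999L, spec = fx_spec3()))

# template-space DSI of one delineation against the forward-warped truth mask
delineation_dsi <- function(del, truth_mask, native_affine) {
  tv <- ct_volume(truth_mask + 0, native_affine, space = "native",
                  units = "scaled")
  truth <- warp_with_chain(tv, del$chain, del$normalized, method = "nearest")
  dsi(del$template_map$labels != 0L, truth$data > 0)
}
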