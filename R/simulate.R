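# Synthetic head phantoms and the simulated-lesion design: a template-shaped
# HU volume (parenchyma ellipsoid with gray/white structure, hypo-intense
# ventricles, hyper-intense skull shell), control cohorts obtained by smooth
# random deformations plus intensity noise, and spherical lesions injected at
# the five published MNI centers with radii 7/10/15/22 mm and contrasts of
# +/-20/40/60 percent of the mean in-brain signal.

#' Phantom specification
#'
#' Tissue values are typical brain-CT Hounsfield units (air -1000, CSF 2,
#' white matter 30, gray matter 36, bone 700). Geometry is an axis-aligned
#' ellipsoidal head centred near the template origin with two lateral
#' ventricles and a thin skull shell. `noise_sd_hu` and
#' `deformation_amplitude_mm` describe the control cohort (about 4 HU image
#' noise; smooth anatomical deformations up to about 3 mm).
#'
#' @param brain_axes_mm ellipsoid semi-axes of the brain
#' @param brain_center_mm world centre of the brain
#' @param ventricle_axes_mm,ventricle_center_mm lateral-ventricle geometry
#'   (mirrored in x)
#' @param white_fraction relative size of the inner white-matter ellipsoid
#' @param skull_thickness_frac skull shell, as a fraction of the brain radius
#' @param csf_rim_frac CSF rim between brain and skull
#' @param hu named tissue intensities (air, csf, white, gray, bone)
#' @param texture_amplitude_hu,texture_wavelength_mm smooth intra-parenchymal
#'   intensity modulation emulating gray/white convolutional structure
#'   (about 8 HU at 20 mm); this is what makes the brain interior carry
#'   registration information, as real parenchyma does
#' @param deformation_amplitude_mm max magnitude of the random smooth
#'   displacement for cohort subjects
#' @param affine_jitter scale of the random affine component (radians /
#'   log-scale units) for cohort subjects
#' @param noise_sd_hu additive Gaussian noise SD inside the head
#' @param resolution_mm,box grid of the phantom (template grid)
#' @param edge_smooth_fwhm_mm partial-volume / scanner point-spread blur
#'   (default 2.5 mm FWHM)
#' @param seed integer; fixes all randomness derived from the spec
#' @return list of class `phantom_spec`
#' @export
phantom_spec <- function(brain_axes_mm = c(68, 86, 62),
                         brain_center_mm = c(0, -18, 12),
                         ventricle_axes_mm = c(6, 22, 8),
                         ventricle_center_mm = c(17, -25, 16),
                         white_fraction = 0.72,
                         skull_thickness_frac = 0.05,
                         csf_rim_frac = 0.015,
                         hu = c(air = -1000, csf = 2, white = 30, gray = 36,
                                bone = 700),
                         texture_amplitude_hu = 8,
                         texture_wavelength_mm = 20,
                         deformation_amplitude_mm = 3,
                         affine_jitter = 0.02,
                         noise_sd_hu = 4,
                         resolution_mm = 1,
                         box = default_bounding_box(),
                         edge_smooth_fwhm_mm = NULL,
                         seed = 1L) {
  stopifnot(hu["air"] < hu["csf"], hu["csf"] < hu["white"],
            hu["white"] <= hu["gray"], hu["gray"] < hu["bone"])
  if (is.null(edge_smooth_fwhm_mm)) edge_smooth_fwhm_mm <- 2.5
  structure(as.list(environment()), class = "phantom_spec")
}

ellipsoid_rho2 <- function(xyz, center, axes) {
  ((xyz[, 1] - center[1]) / axes[1])^2 +
  ((xyz[, 2] - center[2]) / axes[2])^2 +
  ((xyz[, 3] - center[3]) / axes[3])^2
}

#' Generate the head-shaped CT template phantom
#'
#' Deterministic (no noise): gray/white parenchyma ellipsoid, hypo-intense
#' ventricles, a thin CSF rim, a hyper-intense skull shell, air at -1000,
#' blurred slightly to emulate the scanner point-spread function.
#' @param spec a [phantom_spec()]
#' @return `ct_volume` in Hounsfield units, space = template
#' @export
make_phantom_template <- function(spec = phantom_spec()) {
  g <- grid_for_box(spec$box, spec$resolution_mm)
  vol <- ct_volume(array(0, g$dim), g$affine, space = "template",
                   units = "scaled")
  xyz <- grid_world_coords(vol)
  rho <- sqrt(ellipsoid_rho2(xyz, spec$brain_center_mm, spec$brain_axes_mm))
  outer_skull <- 1 + spec$csf_rim_frac + spec$skull_thickness_frac
  if (any(abs(spec$brain_center_mm) + spec$brain_axes_mm * outer_skull >
          pmax(abs(spec$box$min_mm), abs(spec$box$max_mm))))
    stop("phantom geometry exceeds the grid", call. = FALSE)
  hu <- spec$hu
  val <- rep(hu[["air"]], nrow(xyz))
  val[rho <= outer_skull] <- hu[["bone"]]
  val[rho <= 1 + spec$csf_rim_frac] <- hu[["csf"]]
  val[rho <= 1] <- hu[["gray"]]
  val[rho <= spec$white_fraction] <- hu[["white"]]
  if (spec$texture_amplitude_hu > 0) {
    la <- spec$texture_wavelength_mm
    tex <- spec$texture_amplitude_hu *
      sin(2 * pi * xyz[, 1] / la) *
      sin(2 * pi * xyz[, 2] / (1.13 * la)) *
      sin(2 * pi * xyz[, 3] / (0.89 * la))
    inb <- rho <= 1
    val[inb] <- val[inb] + tex[inb]
  }
  vc <- spec$ventricle_center_mm
  for (sx in c(-1, 1)) {
    cen <- c(sx * vc[1], vc[2], vc[3])
    val[ellipsoid_rho2(xyz, cen, spec$ventricle_axes_mm) <= 1 & rho <= 1] <-
      hu[["csf"]]
  }
  arr <- array(val, g$dim)
  if (spec$edge_smooth_fwhm_mm > 0) {
    sig <- fwhm_to_sigma(spec$edge_smooth_fwhm_mm) / spec$resolution_mm
    arr <- smooth_array(arr, rep(sig, 3))
  }
  ct_volume(arr, g$affine, space = "template", units = "hounsfield")
}

# smooth random displacement: coarse white noise (node spacing ~30 mm)
# upsampled to the grid, rescaled so max |d| equals `amplitude`
random_smooth_displacement <- function(grid_vol, amplitude, node_mm = 30) {
  d <- dim(grid_vol$data)
  vs <- voxel_size(grid_vol)
  nd <- pmax(3L, ceiling(d * vs / node_mm))
  Ac <- grid_vol$affine
  Ac[1:3, 1:3] <- Ac[1:3, 1:3] %*% diag((d - 1) / (nd - 1))
  comp <- vector("list", 3L)
  for (a in 1:3) {
    coarse <- array(stats::rnorm(prod(nd)), nd)
    cv <- ct_volume(coarse, Ac, space = "template", units = "scaled")
    comp[[a]] <- resample_to_grid(cv, grid_vol, background = 0)$data
  }
  mx <- max(sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2))
  if (mx > 0 && amplitude > 0) comp <- lapply(comp, function(x) x * amplitude / mx)
  else comp <- lapply(comp, function(x) x * 0)
  comp
}

#' Generate a cohort of control scans from the template phantom
#'
#' Each subject is the template warped by a random smooth displacement (a
#' small random affine component plus a band-limited random field with
#' maximum magnitude `deformation_amplitude_mm`) with additive Gaussian
#' intensity noise inside the head. Subject s is seeded from
#' `spec$seed` via `seed + s`, so cohorts are bit-reproducible.
#'
#' @param template phantom `ct_volume` from [make_phantom_template()]
#' @param n number of subjects (>= 2)
#' @param seed integer; overrides `spec$seed`
#' @param spec the [phantom_spec()] describing deformation/noise
#' @return list of `ct_volume`s (native space, Hounsfield units)
#' @export
make_control_cohort <- function(template, n, seed = NULL,
                                spec = phantom_spec()) {
  stopifnot(n >= 1L)
  if (is.null(seed)) seed <- spec$seed
  lapply(seq_len(n), function(s) {
    simulate_subject(template, seed = as.integer(seed) + s, spec = spec)
  })
}

#' Simulate one subject scan from the template phantom
#' @inheritParams make_control_cohort
#' @param seed subject seed
#' @export
simulate_subject <- function(template, seed, spec = phantom_spec()) {
  set.seed(seed)
  amp <- spec$deformation_amplitude_mm
  aj <- spec$affine_jitter
  d <- dim(template$data)
  center <- as.numeric(vox_to_world(template, matrix((d - 1) / 2, 1)))
  p <- c(stats::rnorm(3, 0, 75 * aj),       # translation, mm
         stats::rnorm(3, 0, aj),            # rotation, rad
         stats::rnorm(3, 0, 0.75 * aj),     # log scale
         stats::rnorm(3, 0, 0.5 * aj))      # shear
  A <- params_to_affine(p, center)
  disp <- random_smooth_displacement(template, amp)
  mp <- function(xyz) {
    out <- sweep(xyz %*% t(A[1:3, 1:3]), 2L, A[1:3, 4L], "+")
    out[, 1] <- out[, 1] + as.numeric(disp[[1]])
    out[, 2] <- out[, 2] + as.numeric(disp[[2]])
    out[, 3] <- out[, 3] + as.numeric(disp[[3]])
    out
  }
  sub <- resample_to_grid(template, template, map = mp, background = -1000,
                          space = "native", units = "hounsfield")
  if (spec$noise_sd_hu > 0) {
    head <- sub$data > -900
    noise <- stats::rnorm(sum(head), 0, spec$noise_sd_hu)
    sub$data[head] <- sub$data[head] + noise
  }
  sub
}

#' Spherical lesion specification
#' @param center_mm world (MNI) coordinates of the sphere centre
#' @param radius_mm sphere radius, mm (> 0)
#' @param delta_pct signed percent intensity change relative to the mean
#'   in-brain signal (>= -100)
#' @export
lesion_spec <- function(center_mm, radius_mm, delta_pct) {
  stopifnot(radius_mm > 0, delta_pct >= -100)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, delta_pct = delta_pct),
            class = "lesion_spec")
}

#' The five published lesion centres (MNI mm)
#' @export
default_lesion_centers <- function() {
  matrix(c(32, 12, -4,
           15, -43, 9,
           3, 55, -5,
           -48, 6, 0,
           -21, 6, -13), ncol = 3L, byrow = TRUE)
}

in_brain_mask <- function(vol, brain_range = c(15, 60)) {
  vol$data > brain_range[1] & vol$data < brain_range[2]
}

#' Inject a spherical lesion into a CT volume
#'
#' The binary mask contains every voxel whose centre lies within
#' `radius_mm` of `center_mm` (world coordinates; voxel-centre inclusion, no
#' partial-volume weighting). Lesion voxels are set (hard replacement) to
#' `mean_brain * (1 + delta_pct / 100)`, where the mean brain signal is taken
#' over the in-head, non-ventricle, non-bone voxels (HU in (15, 300)). With
#' `delta_pct = 0` the image is returned unchanged (the mask is still
#' returned).
#'
#' @param vol `ct_volume` in Hounsfield units
#' @param spec a [lesion_spec()]
#' @return list: `volume` (lesioned copy), `mask` (logical array),
#'   `mean_brain` (the reference intensity), `spec`
#' @export
inject_spherical_lesion <- function(vol, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  brain <- in_brain_mask(vol)
  cv <- round(world_to_vox(vol, matrix(spec$center_mm, 1)))
  d <- dim(vol$data)
  if (any(cv < 0) || any(cv > d - 1))
    stop("lesion center outside the volume grid", call. = FALSE)
  cidx <- 1 + cv[1] + d[1] * (cv[2] + d[2] * cv[3])
  if (!brain[cidx])
    stop("lesion center outside the brain", call. = FALSE)
  xyz <- grid_world_coords(vol)
  r2 <- (xyz[, 1] - spec$center_mm[1])^2 + (xyz[, 2] - spec$center_mm[2])^2 +
        (xyz[, 3] - spec$center_mm[3])^2
  mask <- array(r2 <= spec$radius_mm^2, d)
  mb <- mean(vol$data[brain])
  out <- vol
  if (spec$delta_pct != 0)
    out$data[mask] <- mb * (1 + spec$delta_pct / 100)
  list(volume = out, mask = mask, mean_brain = mb, spec = spec)
}

#' Build the simulated-lesion design
#'
#' Pairs each volume 1:1 with a lesion centre and crosses with all radii and
#' contrast deltas (Cartesian product, one lesion per output image). The
#' defaults (5 scans x 4 radii x 6 deltas) give the 120-image design.
#'
#' @param volumes list of `ct_volume`s (one per centre)
#' @param centers matrix of centres, one row per volume
#'   (default [default_lesion_centers()] recycled/truncated to the volumes)
#' @param radii lesion radii, mm
#' @param deltas signed percent contrasts
#' @return list of cases, each `list(volume, mask, spec, case_id)`
#' @export
generate_simulation_grid <- function(volumes,
                                     centers = default_lesion_centers(),
                                     radii = c(7, 10, 15, 22),
                                     deltas = c(-60, -40, -20, 20, 40, 60)) {
  if (length(volumes) == 0L || length(radii) == 0L || length(deltas) == 0L)
    stop("empty factor list", call. = FALSE)
  centers <- matrix(centers, ncol = 3L)
  if (nrow(centers) < length(volumes))
    stop("need one centre per volume", call. = FALSE)
  cases <- list()
  for (vi in seq_along(volumes)) for (r in radii) for (dl in deltas) {
    sp <- lesion_spec(centers[vi, ], r, dl)
    inj <- inject_spherical_lesion(volumes[[vi]], sp)
    cases[[length(cases) + 1L]] <- list(
      volume = inj$volume, mask = inj$mask, spec = sp,
      case_id = sprintf("v%02d_r%02g_d%+03g", vi, r, dl))
  }
  cases
}
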