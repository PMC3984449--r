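# Two-step normalization: affine warp, intensity-based segmentation, skull
# stripping, deformable registration, reslicing and inverse warping.

test_that("affine normalization recovers known anisotropic scales", {
  ps <- fx_get("ps3", function() transform_intensity(fx_phantom3()))
  truth <- c(1.1, 0.95, 1.05)
  Mtrue <- params_to_affine(c(1, -2, 0.5, 0, 0, 0, log(truth), 0, 0, 0),
                            c(0, -18, 12))
  mov <- resample_to_grid(ps, ps, map = Mtrue, background = 0)
  fit <- affine_normalize(mov, ps)
  # the sampling map inverts the generating one: recovered scales ~ 1/truth
  sc <- sqrt(colSums(fit$transform$matrix[1:3, 1:3]^2))
  expect_lt(max(abs(sc * truth - 1)), 0.02)
  expect_gte(fit$similarity[["after"]], fit$similarity[["before"]])
})

test_that("affine normalization of the template onto itself is identity", {
  ps <- fx_scaled6()
  fit <- affine_normalize(ps, ps)
  expect_lt(max(abs(fit$transform$matrix - diag(4))), 0.02)
})

test_that("segmentation thresholds follow the mean +/- 2 SD rule", {
  set.seed(6)
  arr <- array(rnorm(1e5, 2400, 100), c(50, 50, 40))
  v <- ct_volume(arr, diag(c(3, 3, 3, 1)), units = "scaled")
  v$units <- "scaled"
  m <- segment_masks(v)
  # Gaussian in-head intensities: lower-tail fraction ~ Phi(-2) = 0.0228
  # (+/- 0.005 absolute at 1e5 voxels)
  expect_lt(abs(mean(m$ventricle_mask) - pnorm(-2)), 0.005)
  expect_lt(abs(mean(m$contour_mask) - pnorm(-2)), 0.005)
  expect_equal(m$threshold_low, 2400 - 200, tolerance = 10)
  expect_equal(m$threshold_high, 2400 + 200, tolerance = 10)
  # degenerate: constant in-head intensity
  vc <- ct_volume(array(2400, c(10, 10, 10)), diag(4), units = "scaled")
  vc$units <- "scaled"
  expect_error(segment_masks(vc), "degenerate")
})

test_that("ventricles 4 SD below parenchyma are captured almost entirely", {
  ps <- fx_scaled6()
  sp <- fx_spec6()
  xyz <- grid_world_coords(ps)
  vent <- array(FALSE, dim(ps$data))
  for (sx in c(-1, 1)) {
    cen <- c(sx * sp$ventricle_center_mm[1], sp$ventricle_center_mm[2:3])
    vent <- vent | array(ctlesion:::ellipsoid_rho2(xyz, cen,
                          sp$ventricle_axes_mm) <= 1, dim(ps$data))
  }
  soft <- ps$data > 500 & ps$data <= 3400
  par_med <- median(ps$data[soft]); s <- mad(ps$data[soft])
  ps4 <- ps
  ps4$data[vent] <- par_med - 4 * s
  m <- segment_masks(ps4)
  expect_gte(sum(m$ventricle_mask & vent) / sum(vent), 0.95)
})

test_that("skull stripping zeroes skull ring and ventricular/contour voxels", {
  ps <- fx_scaled6()
  m <- segment_masks(ps)
  st <- skull_strip(ps, m)
  expect_true(all(st$data[!m$in_head] == 0))
  expect_true(all(st$data[m$contour_mask] == 0))
  # bone (the skull ring) is part of the contour mask
  expect_true(all(st$data[ps$data > 3500] == 0))
  keep <- m$in_head & !m$ventricle_mask & !m$contour_mask
  expect_identical(st$data[keep], ps$data[keep])
  # empty masks -> in-head-masked input; full masks -> all background
  m0 <- m
  m0$ventricle_mask[] <- FALSE; m0$contour_mask[] <- FALSE
  expect_identical(skull_strip(ps, m0)$data[m$in_head], ps$data[m$in_head])
  m1 <- m0
  m1$ventricle_mask[] <- TRUE
  expect_true(all(skull_strip(ps, m1)$data == 0))
})

test_that("reslice produces the inclusive bounding-box grid", {
  ps <- fx_scaled6()
  r1 <- reslice(ps, default_bounding_box(), 6)
  expect_true(same_grid(r1, ps))
  expect_lt(max(abs(r1$data - ps$data)), 1e-6 * diff(range(ps$data)))
  r2 <- reslice(ps, default_bounding_box(), 2)
  expect_identical(dim(r2$data), c(91L, 109L, 96L))
  expect_error(reslice(ps, default_bounding_box(), -1), "resolution")
  native <- ps; native$space <- "native"
  expect_error(reslice(native), "template")
})

test_that("deformable registration recovers a smooth sinusoidal field", {
  ph <- fx_phantom3()
  ps <- transform_intensity(ph)
  g <- grid_world_coords(ps)
  d <- dim(ps$data)
  disp <- list(array(3 * sin(2 * pi * g[, 2] / 90), d),
               array(3 * sin(2 * pi * g[, 3] / 90), d),
               array(3 * sin(2 * pi * g[, 1] / 90), d))
  stT <- spatial_transform_displacement(disp, ps$affine)
  mov <- resample_to_grid(ps, ps,
                          map = function(x) x + sample_displacement(stT, x),
                          background = 0)
  str_f <- skull_strip(ps, segment_masks(ps))
  str_m <- skull_strip(mov, segment_masks(mov))
  nl <- nonlinear_normalize(str_m, str_f, mov)
  # reference: the true inverse displacement (sampling convention)
  tru <- sample_displacement(invert_displacement(stT, 40, 0.005), g)
  rec <- sample_displacement(nl$transform, g)
  brain <- as.numeric(ctlesion:::in_brain_mask(ph)) == 1
  rms <- sqrt(mean(rowSums((rec - tru)^2)[brain]))
  expect_lt(rms, 1.5)
  # practically diffeomorphic: Jacobian > 0 on >= 99.5% of in-brain voxels
  jd <- jacobian_determinant(nl$transform)
  expect_gte(mean(jd[array(brain, d)] > 0), 0.995)
  # warping the carrier must not reduce its template correlation
  head <- ps$data > 500
  expect_gte(spatial_correlation(nl$volume, ps, head),
             spatial_correlation(mov, ps, head))
})

test_that("deformable registration of identical inputs is near zero", {
  ps <- fx_scaled6()
  str_f <- skull_strip(ps, segment_masks(ps))
  st <- register_demons(str_f, str_f, background = 0)
  mag <- sqrt(st$disp[[1]]^2 + st$disp[[2]]^2 + st$disp[[3]]^2)
  expect_lt(sqrt(mean(mag^2)), 0.3)
})

test_that("displacement inversion satisfies the round-trip contract", {
  ps <- fx_scaled6()
  g <- grid_world_coords(ps)
  d <- dim(ps$data)
  disp <- list(array(2 * sin(2 * pi * g[, 2] / 80), d),
               array(2 * cos(2 * pi * g[, 3] / 80), d),
               array(0, d))
  st <- spatial_transform_displacement(disp, ps$affine)
  sti <- invert_displacement(st)
  # x -> x + d(x) -> + d_inv(...) should return x within 0.5 mm RMS in-head
  head <- as.numeric(ps$data > 500) == 1
  fwd <- g + sample_displacement(st, g)
  back <- fwd + sample_displacement(sti, fwd)
  expect_lt(sqrt(mean(rowSums((back - g)^2)[head])), 0.5)
})

test_that("inverse_warp round-trips a ternary map through a full chain", {
  ph <- fx_phantom6()
  g <- grid_world_coords(ph)
  d <- dim(ph$data)
  # synthetic chain: small rigid + small affine + smooth displacement
  Mr <- params_to_affine(c(2, -1, 1.5, 0.01, -0.02, 0.015), c(0, -18, 12))
  Ma <- params_to_affine(c(0.5, 0.5, -0.5, 0, 0, 0, log(c(1.04, 0.97, 1.02)),
                           0, 0, 0), c(0, -18, 12))
  disp <- list(array(2 * sin(2 * pi * g[, 2] / 100), d),
               array(2 * sin(2 * pi * g[, 3] / 100), d),
               array(2 * sin(2 * pi * g[, 1] / 100), d))
  chain <- list(spatial_transform_affine(Mr, "rigid"),
                spatial_transform_affine(Ma, "affine"),
                spatial_transform_displacement(disp, ph$affine))
  # native ternary sphere pair (one of each sign)
  r2a <- rowSums(sweep(g, 2, c(20, 0, 10), "-")^2)
  r2b <- rowSums(sweep(g, 2, c(-25, -30, 5), "-")^2)
  lab <- array(0L, d)
  lab[array(r2a <= 15^2, d)] <- 1L
  lab[array(r2b <= 12^2, d)] <- -1L
  native_map <- lesion_map(lab, ph$affine, space = "native")
  vol <- ct_volume(lab + 0, ph$affine, space = "native", units = "scaled")
  warped <- warp_with_chain(vol, chain, ph, method = "nearest")
  tmpl_map <- lesion_map(array(as.integer(warped$data), d), ph$affine,
                         space = "template")
  back <- inverse_warp(tmpl_map, chain, ph)
  expect_true(all(back$labels %in% c(-1L, 0L, 1L)))
  expect_gte(dsi(back$labels != 0L, lab != 0L), 0.90)
  # volume preserved within 10% and signs preserved
  expect_lt(abs(sum(back$labels != 0) / sum(lab != 0) - 1), 0.1)
  expect_gte(dsi(back$labels == 1L, lab == 1L), 0.85)
  # identity chain: map unchanged
  idc <- list(spatial_transform_affine(diag(4)))
  expect_identical(inverse_warp(tmpl_map, idc, ph)$labels, tmpl_map$labels)
})

test_that("grid mismatches in the stripped pair fail fast", {
  ps <- fx_scaled6()
  small <- ct_volume(array(0, c(4, 4, 4)), diag(4), units = "scaled")
  small$units <- "scaled"
  expect_error(nonlinear_normalize(ps, small, ps), "grid mismatch")
  m <- segment_masks(ps)
  expect_error(skull_strip(small, m), "grid mismatch")
})
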