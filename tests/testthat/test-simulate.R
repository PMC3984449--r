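# Phantom generation, control cohorts, lesion injection, the simulation grid.

test_that("the phantom template has the stated tissue structure", {
  ph <- fx_phantom6()
  brain <- ctlesion:::in_brain_mask(ph)
  mb <- mean(ph$data[brain])
  expect_gte(mb, 20); expect_lte(mb, 50)          # mean in-brain HU
  expect_identical(ph$units, "hounsfield")
  expect_identical(ph$space, "template")
  # deterministic construction
  expect_identical(make_phantom_template(fx_spec6())$data, ph$data)
  # intensity ordering is enforced by the spec constructor
  expect_error(phantom_spec(hu = c(air = -1000, csf = 50, white = 30,
                                   gray = 36, bone = 700)))
  # geometry must fit the grid
  expect_error(make_phantom_template(
    phantom_spec(resolution_mm = 6, brain_axes_mm = c(120, 150, 120))),
    "exceeds")
})

test_that("control cohorts are reproducible and well dispersed", {
  ph <- fx_phantom6()
  sp <- fx_spec6()
  co <- make_control_cohort(ph, 6L, seed = 50L, spec = sp)
  co2 <- make_control_cohort(ph, 6L, seed = 50L, spec = sp)
  for (i in seq_along(co)) expect_identical(co[[i]]$data, co2[[i]]$data)
  # different subjects differ
  expect_gt(max(abs(co[[1]]$data - co[[2]]$data)), 1)
  # per-voxel SD positive on nearly all in-brain voxels
  brain <- ctlesion:::in_brain_mask(ph)
  X <- vapply(co, function(v) v$data[brain], numeric(sum(brain)))
  sdv <- apply(X, 1L, sd)
  expect_gte(mean(sdv > 0), 0.99)
  # zero deformation + zero noise + zero jitter -> identical to template
  sp0 <- phantom_spec(resolution_mm = 6, deformation_amplitude_mm = 0,
                      affine_jitter = 0, noise_sd_hu = 0)
  co0 <- make_control_cohort(ph, 2L, seed = 51L, spec = sp0)
  expect_equal(co0[[1]]$data, ph$data, tolerance = 1e-12)
  expect_equal(co0[[2]]$data, ph$data, tolerance = 1e-12)
})

test_that("cohort voxel intensities are approximately Gaussian off-interface", {
  # Within ~one point-spread width of a tissue interface the intensity
  # response to anatomical deformation is nonlinear (a sliding sigmoid), so
  # per-voxel values there are inherently non-Gaussian in ANY sharp-interface
  # head model -- as in real CT, where the SD map is elevated near contours
  # and ventricles. The Gaussian working assumption of the t-test is asserted
  # where it is meant to hold: in-brain voxels away from interfaces (locally
  # flat template neighborhood).
  sp <- fx_spec3()
  ph <- fx_phantom3()
  co <- make_control_cohort(ph, 20L, seed = 60L, spec = sp)
  brain <- ctlesion:::in_brain_mask(ph)
  d <- dim(ph$data); arr <- ph$data
  rng <- array(0, d)
  for (ax in 1:3) {
    ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
    im <- pmax(seq_len(d[ax]) - 1L, 1L)
    dif <- if (ax == 1) abs(arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE])
           else if (ax == 2) abs(arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE])
           else abs(arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE])
    rng <- pmax(rng, array(dif, d))
  }
  flat <- brain & rng < 8          # < 8 HU across the 6-neighborhood
  set.seed(11)
  vox <- sample(which(flat), 250)
  X <- vapply(co, function(v) v$data[vox], numeric(length(vox)))
  p <- apply(X, 1L, function(row) stats::shapiro.test(row)$p.value)
  expect_gte(mean(p > 0.01), 0.90)
})

test_that("spherical masks match the analytic sphere volume", {
  # 1 mm local grid, uniform parenchyma-valued volume
  n <- 61L
  A <- diag(4); A[1:3, 4] <- -(n - 1) / 2
  base <- ct_volume(array(30, c(n, n, n)), A, units = "hounsfield")
  for (r in c(7, 10, 15, 22)) {
    inj <- inject_spherical_lesion(base, lesion_spec(c(0, 0, 0), r, 40))
    expect_lt(abs(sum(inj$mask) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
              0.02)
  }
})

test_that("lesion injection replaces intensities and is exactly recoverable", {
  ph <- fx_phantom6()
  sub <- simulate_subject(ph, seed = 70L, spec = fx_spec6())
  sp <- lesion_spec(c(32, 12, -4), 15, 40)
  inj <- inject_spherical_lesion(sub, sp)
  changed <- inj$volume$data != sub$data
  expect_identical(changed, inj$mask)             # mask exactly recoverable
  expect_equal(unique(inj$volume$data[inj$mask]),
               inj$mean_brain * 1.4, tolerance = 1e-12)
  # delta = 0: image unchanged, mask still returned
  inj0 <- inject_spherical_lesion(sub, lesion_spec(c(32, 12, -4), 15, 0))
  expect_identical(inj0$volume$data, sub$data)
  expect_identical(inj0$mask, inj$mask)
  # centre outside the brain -> error
  expect_error(inject_spherical_lesion(sub, lesion_spec(c(-89, -125, -81),
                                                        7, 40)), "brain")
  expect_error(lesion_spec(c(0, 0, 0), -1, 40))
  expect_error(lesion_spec(c(0, 0, 0), 5, -150))
})

test_that("the simulation grid is the full Cartesian design", {
  ph <- fx_phantom6()
  vols <- make_control_cohort(ph, 5L, seed = 80L, spec = fx_spec6())
  cases <- generate_simulation_grid(vols)
  expect_length(cases, 120L)                      # 5 x 4 x 6
  ids <- vapply(cases, `[[`, "", "case_id")
  expect_identical(anyDuplicated(ids), 0L)
  # each case carries exactly one lesion of its spec
  cs <- cases[[1]]
  expect_identical(sum(cs$volume$data != vols[[1]]$data), sum(cs$mask))
  # degenerate designs
  one <- generate_simulation_grid(vols[1], centers = c(32, 12, -4),
                                  radii = 10, deltas = 40)
  expect_length(one, 1L)
  eight <- generate_simulation_grid(vols[1:2],
                                    centers = default_lesion_centers()[1:2, ],
                                    radii = c(7, 10), deltas = c(-20, 20))
  expect_length(eight, 8L)
  expect_error(generate_simulation_grid(list()), "empty")
  expect_error(generate_simulation_grid(vols, radii = numeric(0)), "empty")
})
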