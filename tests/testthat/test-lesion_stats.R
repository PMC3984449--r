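# Smoothing, the normative control model, the Crawford-Howell t statistic
# and ternary thresholding.

test_that("FWHM/sigma conversion and kernel mass", {
  expect_equal(fwhm_to_sigma(5), 5 / 2.35482, tolerance = 1e-5)
  # impulse response sums to 1 away from boundaries
  arr <- array(0, c(21, 21, 21)); arr[11, 11, 11] <- 1
  v <- ct_volume(arr, diag(4), units = "scaled"); v$units <- "scaled"
  sm <- smooth_volume(v, 5)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  # constant image stays constant in the interior
  vc <- ct_volume(array(7, c(21, 21, 21)), diag(4), units = "scaled")
  vc$units <- "scaled"
  smc <- smooth_volume(vc, 5)
  # interior = voxels at least one kernel radius from every boundary
  expect_equal(smc$data[10:12, 10:12, 10:12], array(7, c(3, 3, 3)),
               tolerance = 1e-9)
  expect_error(smooth_volume(v, 0), "fwhm")
})

make_vols <- function(X, affine = diag(4)) {
  # columns of X -> list of volumes on a common tiny grid
  d <- c(dim(X)[1], 1L, 1L)
  lapply(seq_len(ncol(X)), function(j) {
    v <- ct_volume(array(X[, j], d), affine, units = "scaled")
    v$units <- "scaled"
    v
  })
}

test_that("control model computes sample mean/SD and the brain mask", {
  vols <- make_vols(cbind(c(1, 5), c(3, 5)))
  m <- control_model(vols, fwhm_mm = 5, mask_threshold = 0)
  expect_equal(m$mean_map[1, 1, 1], 2)
  expect_equal(m$sd_map[1, 1, 1], sqrt(2))       # sample SD, denominator n-1
  expect_equal(m$sd_map[2, 1, 1], 0)
  expect_true(m$degenerate[2, 1, 1])
  expect_error(control_model(vols[1]), "at least 2")
  # identical controls -> all degenerate
  vi <- make_vols(cbind(c(1, 2), c(1, 2)))
  expect_true(all(control_model(vi, mask_threshold = 0)$degenerate))
})

test_that("control model is calibrated on iid normal cohorts", {
  set.seed(7)
  n <- 72; nvox <- 2e4
  X <- matrix(rnorm(nvox * n), nvox, n)
  vols <- make_vols(X)
  m <- control_model(vols, fwhm_mm = 5, mask_threshold = -Inf)
  expect_lt(abs(mean(m$mean_map)), 0.05)
  expect_lt(abs(mean(m$sd_map) - 1), 0.05)
})

test_that("Crawford-Howell t matches the hand-computed single-voxel case", {
  vols <- make_vols(cbind(1, 2, 3))
  m <- control_model(vols, fwhm_mm = 5, mask_threshold = 0)
  pat <- make_vols(cbind(5))[[1]]
  t <- crawford_howell_t(pat, m)
  expect_equal(t$df, 2L)
  expect_equal(t$t_map[1, 1, 1], 3 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(t$t_map[1, 1, 1], 2.598076, tolerance = 1e-6)
  # x equal to the control mean -> t = 0
  pat0 <- make_vols(cbind(2))[[1]]
  expect_equal(crawford_howell_t(pat0, m)$t_map[1, 1, 1], 0)
})

# independent scalar oracle: Eq. written out term by term from the raw stack
ch_oracle <- function(x, controls) {
  n <- length(controls)
  cbar <- sum(controls) / n
  ssd <- sum((controls - cbar)^2)
  (x - cbar) / sqrt((n + 1) / (n * (n - 1)) * ssd)
}

test_that("vectorized t equals the brute-force oracle at random voxels", {
  set.seed(8)
  n <- 20; nvox <- 3000
  X <- matrix(rnorm(nvox * n, 2400, 50), nvox, n)
  vols <- make_vols(X)
  m <- control_model(vols, fwhm_mm = 5, mask_threshold = 0)
  x <- rnorm(nvox, 2400, 80)
  pat <- make_vols(cbind(x))[[1]]
  t <- crawford_howell_t(pat, m)
  idx <- sample(nvox, 1000)
  oracle <- vapply(idx, function(i) ch_oracle(x[i], X[i, ]), numeric(1))
  expect_lt(max(abs(t$t_map[cbind(idx, 1, 1)] - oracle)), 1e-10)
})

test_that("thresholding uses the two-tailed Student critical value", {
  # df = 71, alpha = 0.05, single tested voxel -> t_crit ~ 1.9939
  arr <- array(2.5, c(1, 1, 1))
  t <- structure(list(t_map = arr, df = 71L,
                      undefined = array(FALSE, c(1, 1, 1)), affine = diag(4)),
                 class = "t_score_map")
  lm1 <- threshold_tmap(t, alpha = 0.05, correction = "none",
                        brain_mask = array(TRUE, c(1, 1, 1)))
  expect_equal(lm1$t_critical, 1.9939, tolerance = 1e-4)
  expect_identical(lm1$labels[1, 1, 1], 1L)
  expect_error(threshold_tmap(t, 0.05, "none", array(FALSE, c(1, 1, 1))),
               "empty")
})

test_that("lesion labels: antisymmetry, alpha monotonicity, sd=0 exclusion", {
  set.seed(9)
  d <- c(12, 12, 8)
  tm <- array(rnorm(prod(d), 0, 3), d)
  undef <- array(FALSE, d); undef[1, 1, 1] <- TRUE
  t <- structure(list(t_map = tm, df = 19L, undefined = undef,
                      affine = diag(4)), class = "t_score_map")
  mask <- array(TRUE, d)
  lm_a <- threshold_tmap(t, 0.05, "none", mask)
  # negating the t map negates all labels
  tneg <- t; tneg$t_map <- -tm
  lm_n <- threshold_tmap(tneg, 0.05, "none", mask)
  expect_identical(lm_n$labels, -lm_a$labels)
  # shrinking alpha never adds labelled voxels
  lm_b <- threshold_tmap(t, 0.01, "none", mask)
  expect_true(all(lm_b$labels == 0L | lm_b$labels == lm_a$labels))
  expect_lte(sum(lm_b$labels != 0), sum(lm_a$labels != 0))
  # tiny alpha labels (almost) nothing
  lm_0 <- threshold_tmap(t, 1e-12, "none", mask)
  expect_identical(sum(lm_0$labels != 0), 0L)
  # undefined voxels are never labelled
  t$t_map[1, 1, 1] <- 50
  expect_identical(threshold_tmap(t, 0.05, "none", mask)$labels[1, 1, 1], 0L)
  # bonferroni divides alpha by the mask size
  lm_c <- threshold_tmap(t, 0.05, "bonferroni", mask)
  expect_equal(lm_c$t_critical,
               qt(1 - 0.05 / sum(mask) / 2, 19), tolerance = 1e-12)
})

test_that("null calibration: rejection rate approaches alpha", {
  # patient drawn from the control distribution; n = 20 controls
  set.seed(10)
  n <- 20; nvox <- 1e5
  X <- matrix(rnorm(nvox * n), nvox, n)
  m <- control_model(make_vols(X), fwhm_mm = 5, mask_threshold = -Inf)
  pat <- make_vols(cbind(rnorm(nvox)))[[1]]
  t <- crawford_howell_t(pat, m)
  t_crit <- qt(1 - 0.05 / 2, df = 19)
  rate <- mean(abs(t$t_map) > t_crit)
  expect_lt(abs(rate - 0.05) / 0.05, 0.30)
})

test_that("cluster filter removes only sub-threshold clusters", {
  d <- c(20, 20, 10)
  lab <- array(0L, d)
  lab[2:5, 2:5, 2:5] <- 1L            # 64 voxels
  lab[15, 15, 5] <- -1L               # isolated voxel
  lm <- lesion_map(lab, diag(4))
  f <- filter_clusters(lm, min_voxels = 10L)
  expect_identical(sum(f$labels == 1L), 64L)
  expect_identical(sum(f$labels == -1L), 0L)
})
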