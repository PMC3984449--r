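# Separable Gaussian smoothing with constant-zero padding, implemented as one
# sparse band-matrix product per axis (Matrix package).

#' Convert a Gaussian FWHM to its standard deviation
#'
#' sigma = fwhm / (2 * sqrt(2 * ln 2)) = fwhm / 2.35482.
#' @param fwhm_mm full width at half maximum, mm
#' @export
fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

gaussian_band_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3.5 * sigma_vox))
  offs <- (-r):r
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  i <- rep(seq_len(n), each = length(offs))
  j <- i + rep(offs, times = n)
  x <- rep(w, times = n)
  ok <- j >= 1L & j <= n
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = x[ok], dims = c(n, n))
}

smooth_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  # axis 1
  if (sigma_vox[1] > 1e-3) {
    K <- gaussian_band_matrix(d[1], sigma_vox[1])
    arr <- array(as.numeric(K %*% matrix(arr, d[1], d[2] * d[3])), d)
  }
  # axis 2
  if (sigma_vox[2] > 1e-3) {
    K <- gaussian_band_matrix(d[2], sigma_vox[2])
    a2 <- aperm(arr, c(2L, 1L, 3L))
    a2 <- array(as.numeric(K %*% matrix(a2, d[2], d[1] * d[3])), c(d[2], d[1], d[3]))
    arr <- aperm(a2, c(2L, 1L, 3L))
  }
  # axis 3
  if (sigma_vox[3] > 1e-3) {
    K <- gaussian_band_matrix(d[3], sigma_vox[3])
    a3 <- aperm(arr, c(3L, 2L, 1L))
    a3 <- array(as.numeric(K %*% matrix(a3, d[3], d[2] * d[1])), c(d[3], d[2], d[1]))
    arr <- aperm(a3, c(3L, 2L, 1L))
  }
  arr
}

#' Gaussian smoothing of a volume
#'
#' Separable convolution with sigma = fwhm / (2 sqrt(2 ln 2)) per axis,
#' converted from mm to voxels using the voxel size; constant-zero padding
#' (kernel mass is conserved away from the boundaries).
#' @param vol `ct_volume`
#' @param fwhm_mm kernel full width at half maximum, mm (> 0)
#' @return smoothed `ct_volume`
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  if (fwhm_mm <= 0) stop("fwhm must be > 0", call. = FALSE)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size(vol)
  out <- smooth_array(vol$data, sigma_vox)
  v <- ct_volume(out, vol$affine, space = vol$space, units = "scaled")
  v$units <- vol$units
  v
}
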