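#' Discrete 3x3x3 Gaussian kernel
#'
#' The isotropic Gaussian `exp(-(dx^2 + dy^2 + dz^2) / (2 sigma^2))` sampled
#' at the 27 integer offsets of a 3x3x3 support and renormalised to unit sum,
#' so filtering preserves constant fields (and hence mean LAC values). The
#' continuous prefactor cancels in the renormalisation.
#'
#' @param sigma Gaussian width in voxels.
#' @return 3x3x3 numeric array summing to 1.
#' @export
gaussian_kernel3 <- function(sigma) {
  stopifnot(sigma > 0)
  o <- -1:1
  r2 <- outer(outer(o^2, o^2, "+"), o^2, "+")
  k <- exp(-r2 / (2 * sigma^2))
  k / sum(k)
}

# Filter a 3D array with a 3x3x3 kernel; borders handled by edge-replication
# padding so the output keeps the input shape (covers crops thinner than the
# kernel in any axis).
convolve3 <- function(a, kernel) {
  d <- dim(a)
  pz <- c(1L, seq_len(d[1]), d[1])
  py <- c(1L, seq_len(d[2]), d[2])
  px <- c(1L, seq_len(d[3]), d[3])
  p <- a[pz, py, px, drop = FALSE]
  out <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    w <- kernel[dz + 2L, dy + 2L, dx + 2L]
    out <- out + w * p[(seq_len(d[1])) + 1L + dz,
                       (seq_len(d[2])) + 1L + dy,
                       (seq_len(d[3])) + 1L + dx, drop = FALSE]
  }
  out
}

#' Denoise a cluster crop at ten Gaussian scales
#'
#' Applies [gaussian_kernel3()] filters with `sigma = sigma_min, ..., sigma_max`
#' (default 1..10, unit increment) to the raw tomogram crop, producing one
#' denoised volume per scale. Widths below 1 or above 10 voxels add no useful
#' intensity variation at the 35 nm sampling this tool targets.
#'
#' @param tomo_crop 3D array of raw intensities (a cluster's `tomo_crop`).
#' @param sigma_min,sigma_max integer scale range in voxels.
#' @return list with `sigmas` (numeric vector) and `volumes` (list of arrays,
#'   one per sigma, each the shape of `tomo_crop`).
#' @export
build_scale_bank <- function(tomo_crop, sigma_min = 1, sigma_max = 10) {
  stopifnot(sigma_min >= 1, sigma_max >= sigma_min)
  sigmas <- seq(sigma_min, sigma_max, by = 1)
  volumes <- lapply(sigmas, function(s) convolve3(tomo_crop, gaussian_kernel3(s)))
  list(sigmas = sigmas, volumes = volumes)
}
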