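#' Drop initial volumes
#'
#' Removes the first `n` frames (MR signal stabilization) and advances the
#' time origin by `n * TR`, so design-matrix sampling stays on the
#' acquisition clock.
#'
#' @param vol a `volume4d`.
#' @param n number of leading frames to drop (default 2).
#' @return a `volume4d` with `n` fewer frames.
#' @export
drop_initial_volumes <- function(vol, n = 2L) {
  stopifnot(inherits(vol, "volume4d"), n >= 0)
  nt <- n_timepoints(vol)
  if (n >= nt)
    stop(sprintf("cannot drop %d of %d volumes", n, nt))
  if (n == 0L) return(vol)
  volume4d(vol$data[, , , (n + 1L):nt, drop = FALSE], affine = vol$affine,
           tr_seconds = vol$tr_seconds,
           time_origin_s = vol$time_origin_s + n * vol$tr_seconds)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-8) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# Convolve along the first dimension of a matrix with whole-sample reflect
# padding; symmetric kernels conserve the column sums exactly.
conv1_reflect <- function(m, kernel) {
  lk <- length(kernel)
  if (lk == 1L) return(m * kernel)
  r <- (lk - 1L) %/% 2L
  n <- nrow(m)
  if (r >= n) stop("smoothing kernel wider than the image axis")
  pad <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1L), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_len(lk))
    out <- out + kernel[j] * pad[(j):(j + n - 1L), , drop = FALSE]
  out
}

smooth_axis <- function(arr, axis, kernel) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(arr, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- conv1_reflect(m, kernel)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each 3D frame with a separable Gaussian of the requested FWHM in
#' mm (sigma = FWHM / (2 sqrt(2 ln 2))), converted per axis to voxel units
#' from the affine's voxel sizes. Whole-sample reflection at the boundary
#' keeps each frame's spatial mean unchanged. `fwhm_mm = 0` is the identity.
#' No temporal operation is performed.
#'
#' @param vol a `volume4d`.
#' @param fwhm_mm full width at half maximum, mm (default 5).
#' @return smoothed `volume4d`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 5) {
  stopifnot(inherits(vol, "volume4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vd <- voxel_dims(vol$affine)
  dat <- vol$data
  for (ax in 1:3)
    dat <- smooth_axis(dat, ax, gaussian_kernel_1d(sigma_mm / vd[ax]))
  volume4d(dat, affine = vol$affine, tr_seconds = vol$tr_seconds,
           time_origin_s = vol$time_origin_s)
}

#' Grand-mean intensity normalization
#'
#' Rescales the entire 4D dataset by one multiplicative factor so that the
#' mean over all in-mask voxels and all timepoints equals `target`. The mask
#' should cover the brain: background zeros would otherwise distort the
#' factor.
#'
#' @param vol a `volume4d`.
#' @param mask logical 3D brain mask.
#' @param target desired grand mean (default 10000, a common convention; the
#'   choice cancels in all downstream statistics).
#' @return rescaled `volume4d`.
#' @export
grand_mean_normalize <- function(vol, mask, target = 10000) {
  stopifnot(inherits(vol, "volume4d"), is.logical(mask),
            all(dim(mask) == dim(vol$data)[1:3]), any(mask))
  flat <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]))
  gm <- mean(flat[which(mask), ])
  if (!is.finite(gm) || gm <= 0)
    stop("in-mask grand mean must be positive")
  volume4d(vol$data * (target / gm), affine = vol$affine,
           tr_seconds = vol$tr_seconds, time_origin_s = vol$time_origin_s)
}

dilate_mask <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  out <- mask
  idx <- which(mask)
  if (!length(idx)) return(out)
  cc <- arrayInd(idx, dims)
  for (j in seq_len(nrow(offs))) {
    nc <- sweep(cc, 2L, offs[j, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
          nc[, 2] >= 1 & nc[, 2] <= dims[2] &
          nc[, 3] >= 1 & nc[, 3] <= dims[3]
    out[nc[ok, , drop = FALSE]] <- TRUE
  }
  out
}

#' Nuisance-extraction masks away from gray matter
#'
#' WM and CSF timecourses serve as covariates of no interest; extracting
#' them from voxels bordering gray matter lets spatial smoothing bleed
#' GM signal (activation, seed networks) into the covariates, which then
#' re-enters every voxel's fit with the opposite sign. Following standard
#' practice, the extraction masks exclude a one-voxel (26-neighborhood)
#' dilation of the GM mask. Falls back to the raw mask with a warning if
#' the exclusion would empty it.
#'
#' @param tissue list with logical `gm`, `wm`, `csf` masks.
#' @return list with logical `wm` and `csf` extraction masks.
#' @export
nuisance_extraction_masks <- function(tissue) {
  halo <- dilate_mask(tissue$gm)
  out <- list(wm = tissue$wm & !halo, csf = tissue$csf & !halo)
  for (nm in c("wm", "csf")) {
    if (!any(out[[nm]])) {
      warning(sprintf(
        "eroded %s mask is empty; falling back to the full mask", nm))
      out[[nm]] <- tissue[[nm]]
    }
  }
  out
}

#' Mean timecourse over a mask
#'
#' @param vol a `volume4d`.
#' @param mask nonempty logical 3D mask on the same grid.
#' @return numeric vector: per-frame arithmetic mean over mask voxels.
#' @export
mean_timecourse <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"), is.logical(mask),
            all(dim(mask) == dim(vol$data)[1:3]))
  if (!any(mask)) stop("mask is empty")
  flat <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]))
  colMeans(flat[which(mask), , drop = FALSE])
}
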