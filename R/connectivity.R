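#' Final steady-state window
#'
#' Keeps the last `floor(minutes * 60 / TR)` frames, where the drug effect is
#' in steady state and connectivity can be estimated free of the ramp.
#'
#' @param vol a `volume4d`.
#' @param minutes window length (default 5).
#' @return windowed `volume4d`.
#' @export
last_window <- function(vol, minutes = 5) {
  stopifnot(inherits(vol, "volume4d"), minutes > 0)
  nt <- n_timepoints(vol)
  nf <- floor(minutes * 60 / vol$tr_seconds)
  if (nf > nt)
    stop(sprintf("window of %d frames exceeds scan length %d", nf, nt))
  if (nf < 2L) stop("window must contain at least 2 frames")
  keep <- (nt - nf + 1L):nt
  volume4d(vol$data[, , , keep, drop = FALSE], affine = vol$affine,
           tr_seconds = vol$tr_seconds,
           time_origin_s = vol$time_origin_s + (nt - nf) * vol$tr_seconds)
}

#' Seed mean timecourse
#'
#' @param vol a `volume4d`.
#' @param roi nonempty logical 3D seed mask.
#' @return per-frame mean over ROI voxels.
#' @export
seed_timecourse <- function(vol, roi) {
  if (!any(roi)) stop("seed ROI is empty")
  mean_timecourse(vol, roi)
}

#' Nuisance matrix for connectivity
#'
#' Intercept, mean-centered linear drift recomputed on the analysis window,
#' and mean-centered WM and CSF timecourses.
#'
#' @param n number of frames in the window.
#' @param wm_tc,csf_tc tissue timecourses on the same window.
#' @return n x 4 matrix with named columns.
#' @export
fc_nuisance_matrix <- function(n, wm_tc, csf_tc) {
  stopifnot(length(wm_tc) == n, length(csf_tc) == n)
  cbind(intercept = rep(1, n),
        drift = seq_len(n) - (n + 1) / 2,
        wm = wm_tc - mean(wm_tc),
        csf = csf_tc - mean(csf_tc))
}

#' Seed-based partial-correlation map
#'
#' For every in-mask voxel, the Pearson correlation between the voxel and
#' seed timecourses after least-squares removal of the nuisance regressors
#' from both; variance-stabilized with the Fisher z-transform (atanh), with
#' |r| clipped at 1 - 1e-7. Zero-variance residuals give r = 0 and are
#' flagged.
#'
#' @param vol a `volume4d` (typically the output of [last_window()]).
#' @param seed_tc seed timecourse, one value per frame.
#' @param nuisance matrix of nuisance regressors including an intercept (or
#'   other constant column).
#' @param mask logical 3D analysis mask.
#' @return list of class `fc_map` with 3D maps `r`, `fisher_z`, logical
#'   `flagged`, plus `n_timepoints` and `n_nuisance`.
#' @export
partial_correlation_map <- function(vol, seed_tc, nuisance, mask) {
  stopifnot(inherits(vol, "volume4d"))
  nt <- n_timepoints(vol)
  if (length(seed_tc) != nt || nrow(nuisance) != nt)
    stop("seed and nuisance must match the number of frames")
  has_const <- any(apply(nuisance, 2L, function(col)
    all(col == col[1]) && col[1] != 0))
  if (!has_const)
    stop("nuisance matrix must include an intercept (constant column)")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  flat <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]))
  Y <- t(flat[idx, , drop = FALSE])
  qrN <- qr(nuisance)
  sres <- qr.resid(qrN, seed_tc)
  Yres <- qr.resid(qrN, Y)
  snorm <- sqrt(sum(sres^2))
  ynorm <- sqrt(colSums(Yres^2))
  r <- numeric(length(idx))
  flag <- ynorm <= 1e-12 * max(ynorm, 1) | snorm <= 1e-12
  ok <- !flag
  if (snorm > 0)
    r[ok] <- as.numeric(crossprod(sres, Yres[, ok, drop = FALSE])) /
      (snorm * ynorm[ok])
  clip_hit <- abs(r) >= 1 - 1e-7
  r <- pmin(1 - 1e-7, pmax(-(1 - 1e-7), r))
  if (any(flag))
    warning(sprintf("%d voxel(s) with zero-variance residual; r set to 0",
                    sum(flag)))
  to_map <- function(v) { m <- array(NA_real_, dim(mask)); m[idx] <- v; m }
  fmap <- array(FALSE, dim(mask)); fmap[idx] <- flag | clip_hit
  structure(list(r = to_map(r), fisher_z = to_map(atanh(r)),
                 flagged = fmap, n_timepoints = nt,
                 n_nuisance = ncol(nuisance)),
            class = "fc_map")
}

#' Group-level paired connectivity contrast with mixture inference
#'
#' Fisher-z maps from both conditions enter a paired t contrast
#' ([paired_contrast()]); the resulting z map is then fed to the spatially
#' regularized mixture model ([icm_fit()]), whose activation and
#' deactivation PPMs (thresholded at > `ppm_threshold`) give the A>B and
#' B>A connectivity-difference masks.
#'
#' @param fc_A,fc_B equal-length lists of `fc_map`s, paired by position.
#' @param mask logical 3D analysis mask.
#' @param ppm_threshold detection threshold on the PPM (default 0.5).
#' @param mrf_beta passed to [icm_fit()] (NULL = estimate).
#' @return list with the `paired_group` result, the `mixture_fit`, and
#'   logical masks `mask_AgtB`, `mask_BgtA`.
#' @export
group_fc_contrast <- function(fc_A, fc_B, mask, ppm_threshold = 0.5,
                              mrf_beta = NULL) {
  zs_A <- lapply(fc_A, function(f) f$fisher_z)
  zs_B <- lapply(fc_B, function(f) f$fisher_z)
  grp <- paired_contrast(zs_A, zs_B, mask)
  zv <- grp$zstat_AgtB[grp$mask]
  if (diff(range(zv)) < 1e-10) {
    # no connectivity difference anywhere: nothing to model
    empty <- array(FALSE, dim(mask))
    return(list(group = grp, fit = NULL,
                mask_AgtB = empty, mask_BgtA = empty))
  }
  fit <- icm_fit(grp$zstat_AgtB, grp$mask, mrf_beta = mrf_beta)
  list(group = grp, fit = fit,
       mask_AgtB = threshold_ppm(fit$ppm_act, ppm_threshold),
       mask_BgtA = threshold_ppm(fit$ppm_deact, ppm_threshold))
}
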