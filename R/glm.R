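#' t-to-z transform by matched quantiles
#'
#' Maps a t statistic with `dof` degrees of freedom to the standard normal
#' quantile with the same tail probability, computed on the log scale for
#' numerical stability in the far tails. Monotone and odd; clipped at
#' |z| = 8, beyond any plausible inference boundary.
#'
#' @param t numeric vector of t statistics.
#' @param dof degrees of freedom.
#' @return z statistics, |z| <= 8.
#' @export
t_to_z <- function(t, dof) {
  stopifnot(dof >= 1)
  z <- sign(t) * stats::qnorm(
    stats::pt(abs(t), df = dof, lower.tail = FALSE, log.p = TRUE),
    lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  pmin(8, pmax(-8, z))
}

#' Voxelwise infusion GLM
#'
#' Ordinary least squares with Gaussian errors at every in-mask voxel. The
#' statistic of interest is the infusion-EV coefficient (the infusion
#' amplitude); its standard error uses the residual variance with
#' dof = n - rank(design), and the z map is the t-to-z transform of
#' amplitude / se. No prewhitening (no autocorrelation model) and no temporal
#' filtering.
#'
#' @param vol a `volume4d`, frames matching the design rows.
#' @param design a `design_matrix` whose first column is `infusion_ev`.
#' @param mask logical 3D analysis mask.
#' @return list of class `subject_glm` with 3D maps `amplitude`, `se`,
#'   `zstat` (NA outside the mask), plus `dof` and `mask`.
#' @export
fit_voxelwise_glm <- function(vol, design, mask) {
  stopifnot(inherits(vol, "volume4d"), is.logical(mask),
            all(dim(mask) == dim(vol$data)[1:3]))
  X <- unclass(design)
  nt <- n_timepoints(vol)
  if (nrow(X) != nt)
    stop("design rows must equal the number of frames")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  flat <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]))
  Y <- t(flat[idx, , drop = FALSE])          # time x voxel

  qrX <- qr(X)
  rank <- qrX$rank
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  dof <- nt - rank
  rss <- colSums(res^2)
  xtx_inv <- chol2inv(qr.R(qrX))
  c_amp <- xtx_inv[1, 1]
  sigma2 <- rss / dof
  amp <- beta[1, ]
  se <- sqrt(sigma2 * c_amp)

  z <- numeric(length(amp))
  ok <- se > 0
  z[ok] <- t_to_z(amp[ok] / se[ok], dof)
  if (any(!ok)) {
    warning(sprintf(
      "%d voxel(s) with zero residual variance; z set to sign(amplitude) * 8",
      sum(!ok)))
    z[!ok] <- sign(amp[!ok]) * 8
  }

  to_map <- function(v) {
    m <- array(NA_real_, dim(mask)); m[idx] <- v; m
  }
  structure(list(amplitude = to_map(amp), se = to_map(se),
                 zstat = to_map(z), dof = dof, mask = mask,
                 coef_names = colnames(X)),
            class = "subject_glm")
}

#' Write a design matrix as TSV for audit
#' @param design a `design_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(unclass(design)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
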