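#' @title Spatially regularized mixture inference on z maps
#' @description
#' Alternative-hypothesis testing of a statistic map: the z values are
#' modelled as a K-class Gaussian mixture (deactivated / null / activated)
#' whose class labels carry a Markov random field soft-max prior encouraging
#' spatially neighboring voxels to share a label. Mixture parameters and the
#' MRF coupling are estimated from the data by iterated conditional modes;
#' the posterior probability map (PPM) of activation, conditional on the
#' estimated neighborhood labels and the data, is thresholded at PPM > 0.5.
#' @name mrf_ppm
NULL

# 6-connected neighbor table: for each in-mask voxel (row), the rank of each
# existing in-mask neighbor among mask voxels, NA otherwise.
neighbor_table <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  rank <- array(NA_integer_, dims)
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  nbr <- matrix(NA_integer_, length(idx), 6L)
  for (j in 1:6) {
    nc <- sweep(coords, 2L, offs[j, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
          nc[, 2] >= 1 & nc[, 2] <= dims[2] &
          nc[, 3] >= 1 & nc[, 3] <= dims[3]
    lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * dims[1] +
      (nc[ok, 3] - 1L) * dims[1] * dims[2]
    nbr[ok, j] <- rank[lin]
  }
  nbr
}

# per-voxel neighbor label counts, nvox x K
neighbor_counts <- function(lab, nbr, K) {
  M <- matrix(0L, length(lab), K)
  for (j in 1:6) {
    nl <- lab[nbr[, j]]
    has <- !is.na(nbr[, j])
    for (k in seq_len(K))
      M[, k] <- M[, k] + (has & !is.na(nl) & nl == k)
  }
  M
}

#' Initialize the mixture on a z map
#'
#' The null class starts at the trimmed mean and sd of the in-mask z
#' distribution; activated and deactivated classes start at the null mean
#' +/- (2 + null sd) with unit sd and mixing 0.05 each. Labels are assigned
#' by nearest class mean; the MRF coupling starts at 0.
#'
#' @param zmap 3D statistic map.
#' @param mask logical 3D mask with at least 50 voxels.
#' @param trim fraction trimmed from each tail for the null moments.
#' @return list of class `mixture_fit`.
#' @export
init_mixture <- function(zmap, mask, trim = 0.1) {
  stopifnot(all(dim(zmap) == dim(mask)))
  idx <- which(mask)
  if (length(idx) < 50L) stop("need at least 50 in-mask voxels")
  z <- zmap[idx]
  if (!all(is.finite(z))) stop("z map must be finite inside the mask")
  if (diff(range(z)) < 1e-10) stop("degenerate (constant) z map")
  q <- stats::quantile(z, c(trim, 1 - trim), names = FALSE)
  zz <- z[z >= q[1] & z <= q[2]]
  mu0 <- mean(zz); s0 <- stats::sd(zz)
  if (!is.finite(s0) || s0 < 0.05) s0 <- 0.05
  means <- c(mu0 - (2 + s0), mu0, mu0 + (2 + s0))
  sds <- c(1, s0, 1)
  mixing <- c(0.05, 0.9, 0.05)
  lab_vec <- apply(abs(outer(z, means, "-")), 1L, which.min)
  labels <- array(NA_integer_, dim(mask))
  labels[idx] <- lab_vec
  structure(list(K = 3L, means = means, sds = sds, mixing = mixing,
                 signs = c(-1L, 0L, 1L), mrf_beta = 0,
                 labels = labels, mask = mask,
                 n_icm_sweeps = 0L, converged = FALSE,
                 objective_trace = numeric(0)),
            class = "mixture_fit")
}

#' MRF soft-max label prior at one voxel
#'
#' p_k proportional to mixing_k * exp(mrf_beta * m_k), where m_k counts the
#' 6-connected in-mask neighbors currently carrying label k. With
#' mrf_beta = 0 this reduces to the global mixing proportions.
#'
#' @param labels 3D integer label array (NA outside the mask).
#' @param voxel length-3 voxel index (1-based), inside the mask.
#' @param mrf_beta nonnegative coupling strength.
#' @param mixing global mixing proportions (length K).
#' @return normalized per-class prior probabilities.
#' @export
neighbor_prior <- function(labels, voxel, mrf_beta, mixing) {
  stopifnot(length(voxel) == 3L, mrf_beta >= 0)
  dims <- dim(labels)
  if (is.na(labels[voxel[1], voxel[2], voxel[3]]))
    stop("voxel is outside the mask")
  K <- length(mixing)
  m <- numeric(K)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (j in 1:6) {
    v <- voxel + offs[j, ]
    if (all(v >= 1) && all(v <= dims)) {
      l <- labels[v[1], v[2], v[3]]
      if (!is.na(l)) m[l] <- m[l] + 1
    }
  }
  w <- log(mixing) + mrf_beta * m
  w <- exp(w - max(w))
  w / sum(w)
}

# joint pseudo-posterior: likelihood + field term with each 6-edge counted once
joint_objective <- function(lab, L, logpi, beta, nbr) {
  conc <- 0L
  for (j in 1:6) {
    nl <- lab[nbr[, j]]
    conc <- conc + sum(!is.na(nl) & nl == lab, na.rm = TRUE)
  }
  sum(L[cbind(seq_along(lab), lab)]) + sum(logpi[lab]) + beta * conc / 2
}

besag_pseudolik <- function(beta, M, lab, logpi) {
  S <- sweep(beta * M, 2L, logpi, "+")
  mx <- apply(S, 1L, max)
  sum(S[cbind(seq_along(lab), lab)] - (mx + log(rowSums(exp(S - mx)))))
}

#' Fit the mixture + MRF by iterated conditional modes
#'
#' Alternates (a) a raster-order label sweep in which each voxel takes the
#' class maximizing neighbor-prior times Gaussian likelihood, (b) weighted
#' maximum-likelihood updates of class means, sds and mixing from the hard
#' labels, and (c) an update of the MRF coupling by maximizing the Besag
#' pseudo-likelihood of the label field over [0, 5]. Stops when a sweep
#' changes no label or after `max_sweeps`. The joint pseudo-posterior is
#' recorded before and after every label sweep and is non-decreasing within
#' each sweep (fixed parameters). A class losing all members is removed with
#' a warning; sds are floored at 0.05. Raster order makes the fit
#' deterministic.
#'
#' @param zmap 3D statistic map.
#' @param mask logical 3D mask.
#' @param max_sweeps maximum ICM sweeps (default 50).
#' @param mrf_beta NULL to estimate adaptively, or a fixed nonnegative value
#'   (0 turns spatial coupling off, giving a plain hard-assignment GMM).
#' @param init optional `mixture_fit` from [init_mixture()].
#' @return a converged `mixture_fit` including `ppm_act`, `ppm_deact` and the
#'   per-sweep objective trace (matrix with columns `before`, `after`).
#' @export
icm_fit <- function(zmap, mask, max_sweeps = 50L, mrf_beta = NULL,
                    init = NULL) {
  fit <- if (is.null(init)) init_mixture(zmap, mask) else init
  estimate_beta <- is.null(mrf_beta)
  beta <- if (estimate_beta) fit$mrf_beta else mrf_beta
  stopifnot(beta >= 0)

  idx <- which(mask)
  z <- zmap[idx]
  n <- length(z)
  nbr <- neighbor_table(mask)
  lab <- fit$labels[idx]
  K <- fit$K
  means <- fit$means; sds <- fit$sds; mixing <- fit$mixing; signs <- fit$signs

  trace <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("before", "after")))
  converged <- FALSE
  sweeps <- 0L
  nbr_list <- lapply(seq_len(n), function(i) nbr[i, !is.na(nbr[i, ])])

  repeat {
    if (sweeps >= max_sweeps) break
    sweeps <- sweeps + 1L
    L <- vapply(seq_len(K), function(k)
      stats::dnorm(z, means[k], sds[k], log = TRUE), numeric(n))
    logpi <- log(mixing)

    j_before <- joint_objective(lab, L, logpi, beta, nbr)
    changes <- 0L
    for (i in seq_len(n)) {
      nb <- nbr_list[[i]]
      m <- tabulate(lab[nb], nbins = K)
      sc <- logpi + beta * m + L[i, ]
      new <- which.max(sc)
      if (new != lab[i]) { lab[i] <- new; changes <- changes + 1L }
    }
    j_after <- joint_objective(lab, L, logpi, beta, nbr)
    trace <- rbind(trace, c(j_before, j_after))

    # parameter update from hard labels
    nk <- tabulate(lab, nbins = K)
    if (any(nk == 0L)) {
      drop <- which(nk == 0L)
      warning(sprintf("class collapse: removing %d empty class(es) [sign %s]",
                      length(drop), paste(signs[drop], collapse = ",")))
      keep <- setdiff(seq_len(K), drop)
      remap <- integer(K); remap[keep] <- seq_along(keep)
      lab <- remap[lab]
      means <- means[keep]; sds <- sds[keep]
      mixing <- mixing[keep]; signs <- signs[keep]
      K <- length(keep)
      nk <- tabulate(lab, nbins = K)
      nbr_list <- nbr_list   # unchanged
    }
    for (k in seq_len(K)) {
      zk <- z[lab == k]
      means[k] <- mean(zk)
      sds[k] <- max(if (length(zk) > 1) stats::sd(zk) else 0.05, 0.05)
    }
    mixing <- nk / n
    # keep the mean ordering deactivated < null < activated
    ord <- order(means)
    if (any(ord != seq_len(K))) {
      remap <- integer(K); remap[ord] <- seq_len(K)
      lab <- remap[lab]
      means <- means[ord]; sds <- sds[ord]
      mixing <- mixing[ord]; signs <- signs[ord]
    }

    if (estimate_beta && K > 1L) {
      M <- neighbor_counts(lab, nbr, K)
      beta <- stats::optimize(besag_pseudolik, c(0, 5), M = M, lab = lab,
                              logpi = log(mixing), maximum = TRUE)$maximum
    }

    if (changes == 0L) { converged <- TRUE; break }
  }

  labels <- array(NA_integer_, dim(mask))
  labels[idx] <- lab
  fit$K <- K; fit$means <- means; fit$sds <- sds; fit$mixing <- mixing
  fit$signs <- signs; fit$mrf_beta <- beta; fit$labels <- labels
  fit$n_icm_sweeps <- sweeps; fit$converged <- converged
  fit$objective_trace <- trace
  ppm <- compute_ppm(zmap, fit)
  fit$ppm_act <- ppm$ppm_act
  fit$ppm_deact <- ppm$ppm_deact
  fit
}

#' Posterior probability maps from a fitted mixture
#'
#' ppm_k(v) = prior_k(v) N(z_v; mu_k, sd_k^2) / sum_j prior_j(v) N(z_v; ...),
#' with the prior from the MRF soft-max at the converged labels. `ppm_act`
#' sums the responsibilities of positive-mean (activated) classes,
#' `ppm_deact` those of negative-mean classes; a removed class contributes 0.
#'
#' @param zmap 3D statistic map.
#' @param fit a `mixture_fit`.
#' @return list with 3D maps `ppm_act` and `ppm_deact` (NA outside mask).
#' @export
compute_ppm <- function(zmap, fit) {
  mask <- fit$mask
  idx <- which(mask)
  z <- zmap[idx]
  n <- length(z)
  K <- fit$K
  nbr <- neighbor_table(mask)
  lab <- fit$labels[idx]
  M <- neighbor_counts(lab, nbr, K)
  S <- sweep(fit$mrf_beta * M, 2L, log(fit$mixing), "+")
  for (k in seq_len(K))
    S[, k] <- S[, k] + stats::dnorm(z, fit$means[k], fit$sds[k], log = TRUE)
  mx <- apply(S, 1L, max)
  P <- exp(S - mx)
  P <- P / rowSums(P)
  to_map <- function(v) { m <- array(NA_real_, dim(mask)); m[idx] <- v; m }
  act <- fit$signs > 0L
  deact <- fit$signs < 0L
  list(ppm_act = to_map(if (any(act)) rowSums(P[, act, drop = FALSE]) else rep(0, n)),
       ppm_deact = to_map(if (any(deact)) rowSums(P[, deact, drop = FALSE]) else rep(0, n)))
}

#' Threshold a posterior probability map
#'
#' Strict inequality: a voxel at exactly the threshold is excluded.
#'
#' @param ppm 3D map in [0, 1] (NA treated as not suprathreshold).
#' @param threshold detection threshold (default 0.5).
#' @return logical 3D mask `ppm > threshold`.
#' @export
threshold_ppm <- function(ppm, threshold = 0.5) {
  out <- ppm > threshold
  out[is.na(out)] <- FALSE
  out
}
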