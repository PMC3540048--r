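# Shared fixtures: small grids and an independent plain-GMM oracle.

tiny_grid <- c(12L, 12L, 8L)

tiny_cohort_spec <- function(n_subjects = 3, noise_sd = 1, effects = list(),
                             seed_network = NULL, rng_seed = 11L, ...) {
  cohort_spec(n_subjects = n_subjects,
              acquisition = acquisition_spec(grid_dims = tiny_grid),
              effects = effects, noise_sd = noise_sd,
              seed_network = seed_network, rng_seed = rng_seed, ...)
}

full_mask <- function(dims) array(TRUE, dims)

# Independent oracle: hard-assignment (classification) Gaussian mixture with
# no spatial term, run from the same initialization as the ICM engine. Used
# to verify that the MRF model with coupling fixed at 0 reduces exactly to a
# non-spatial mixture.
oracle_gmm_classify <- function(z, init_means, init_sds, init_mixing,
                                max_iter = 200, sd_floor = 0.05) {
  K <- length(init_means)
  means <- init_means; sds <- init_sds; mixing <- init_mixing
  lab <- apply(abs(outer(z, means, "-")), 1L, which.min)
  for (it in seq_len(max_iter)) {
    scores <- vapply(seq_len(K), function(k)
      log(mixing[k]) + stats::dnorm(z, means[k], sds[k], log = TRUE),
      numeric(length(z)))
    new_lab <- max.col(scores, ties.method = "first")
    changed <- any(new_lab != lab)
    lab <- new_lab
    nk <- tabulate(lab, nbins = K)
    if (any(nk == 0L)) {
      keep <- which(nk > 0L)
      remap <- integer(K); remap[keep] <- seq_along(keep)
      lab <- remap[lab]
      means <- means[keep]; sds <- sds[keep]; mixing <- mixing[keep]
      K <- length(keep)
      nk <- tabulate(lab, nbins = K)
    }
    for (k in seq_len(K)) {
      zk <- z[lab == k]
      means[k] <- mean(zk)
      sds[k] <- max(if (length(zk) > 1) stats::sd(zk) else sd_floor, sd_floor)
    }
    mixing <- nk / length(z)
    ord <- order(means)
    if (any(ord != seq_len(K))) {
      remap <- integer(K); remap[ord] <- seq_len(K)
      lab <- remap[lab]
      means <- means[ord]; sds <- sds[ord]; mixing <- mixing[ord]
    }
    if (!changed) break
  }
  resp <- vapply(seq_len(K), function(k)
    mixing[k] * stats::dnorm(z, means[k], sds[k]), numeric(length(z)))
  resp <- resp / rowSums(resp)
  list(labels = lab, means = means, sds = sds, mixing = mixing, resp = resp,
       K = K)
}
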