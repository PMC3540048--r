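zmap_with_blobs <- function(dims = c(14L, 14L, 8L), seed = 5L, level = 6) {
  set.seed(seed)
  z <- array(rnorm(prod(dims)), dims)
  blob1 <- ellipsoid_mask(dims, c(4, 4, 4), c(2, 2, 1.6))
  blob2 <- ellipsoid_mask(dims, c(10, 10, 5), c(2.2, 2.2, 1.6))
  z[blob1] <- z[blob1] + level
  z[blob2] <- z[blob2] + level
  list(z = z, truth = blob1 | blob2)
}

test_that("mixture initialization centers the null class on the bulk", {
  set.seed(1)
  dims <- c(22L, 22L, 21L)            # ~10k voxels
  z <- array(rnorm(prod(dims)), dims)
  mask <- full_mask(dims)
  fit <- init_mixture(z, mask)
  expect_lt(abs(fit$means[2]), 0.1)
  expect_equal(fit$K, 3L)
  expect_true(all(fit$mixing > 0))
  expect_true(all(diff(fit$means) > 0))
  expect_error(init_mixture(array(1, dims), mask), "degenerate")
  small <- array(FALSE, dims); small[1:10] <- TRUE
  expect_error(init_mixture(z, small), "50")
})

test_that("neighbor prior follows the soft-max form", {
  dims <- c(3L, 3L, 3L)
  labels <- array(NA_integer_, dims)
  labels[] <- 2L
  # center voxel with all 6 face neighbors activated
  labels[2, 2, 1] <- 3L; labels[2, 2, 3] <- 3L
  labels[2, 1, 2] <- 3L; labels[2, 3, 2] <- 3L
  labels[1, 2, 2] <- 3L; labels[3, 2, 2] <- 3L
  uni <- rep(1 / 3, 3)
  p0 <- neighbor_prior(labels, c(2, 2, 2), mrf_beta = 0, mixing = uni)
  expect_equal(p0, uni)
  pi2 <- c(0.2, 0.7, 0.1)
  expect_equal(neighbor_prior(labels, c(2, 2, 2), 0, pi2), pi2)

  p1 <- neighbor_prior(labels, c(2, 2, 2), mrf_beta = 1, mixing = uni)
  expect_equal(p1[3], exp(6) / (exp(6) + 2), tolerance = 1e-12)

  # neighbors split 3/3 between two classes tie under a uniform prior
  labels[2, 2, 1] <- 1L; labels[2, 2, 3] <- 1L; labels[2, 1, 2] <- 1L
  p2 <- neighbor_prior(labels, c(2, 2, 2), mrf_beta = 1.3, mixing = uni)
  expect_equal(p2[1], p2[3])
})

test_that("with coupling off the fit reduces to a plain classification GMM", {
  zb <- zmap_with_blobs()
  mask <- full_mask(dim(zb$z))
  init <- init_mixture(zb$z, mask)
  fit <- icm_fit(zb$z, mask, mrf_beta = 0, init = init)
  oracle <- oracle_gmm_classify(zb$z[mask], init$means, init$sds, init$mixing)
  expect_identical(as.integer(fit$labels[mask]), as.integer(oracle$labels))
  act_cols <- which(fit$signs > 0)
  expect_equal(fit$ppm_act[mask],
               rowSums(oracle$resp[, act_cols, drop = FALSE]),
               tolerance = 1e-12)
  expect_equal(fit$means, oracle$means, tolerance = 1e-12)
})

test_that("ICM recovers planted blobs and keeps the objective monotone", {
  zb <- zmap_with_blobs()
  mask <- full_mask(dim(zb$z))
  fit <- suppressWarnings(icm_fit(zb$z, mask))
  det <- threshold_ppm(fit$ppm_act, 0.5)
  expect_gte(dice(det, zb$truth), 0.9)
  tr <- fit$objective_trace
  expect_true(all(tr[, "after"] >= tr[, "before"] - 1e-9))
  expect_true(fit$converged)
  expect_true(all(diff(fit$means) > 0))
})

test_that("a pure-null z map yields almost no non-null labels", {
  set.seed(12)
  dims <- c(22L, 22L, 21L)
  z <- array(rnorm(prod(dims)), dims)
  mask <- full_mask(dims)
  fit <- suppressWarnings(icm_fit(z, mask))
  null_class <- which(fit$signs == 0)
  frac_nonnull <- mean(fit$labels[mask] != null_class)
  expect_lt(frac_nonnull, 0.005)
  for (k in which(fit$signs != 0))
    expect_lt(fit$mixing[k], 0.01)
})

test_that("negating the z map swaps activation and deactivation", {
  zb <- zmap_with_blobs(seed = 6)
  mask <- full_mask(dim(zb$z))
  f1 <- suppressWarnings(icm_fit(zb$z, mask))
  f2 <- suppressWarnings(icm_fit(-zb$z, mask))
  expect_equal(f2$ppm_deact, f1$ppm_act, tolerance = 1e-9)
  expect_equal(f2$ppm_act, f1$ppm_deact, tolerance = 1e-9)
  expect_equal(sort(f2$means), sort(-f1$means), tolerance = 1e-9)
})

test_that("spatial coupling suppresses isolated single-voxel activations", {
  isolated_count <- function(det) {
    n <- 0L
    dims <- dim(det)
    for (v in which(det)) {
      ci <- arrayInd(v, dims)
      alone <- TRUE
      for (d in 1:3) for (s in c(-1L, 1L)) {
        ni <- ci; ni[d] <- ni[d] + s
        if (all(ni >= 1) && all(ni <= dims) && det[ni]) alone <- FALSE
      }
      if (alone) n <- n + 1L
    }
    n
  }
  dims <- c(12L, 12L, 6L)
  mask <- full_mask(dims)
  blob <- ellipsoid_mask(dims, c(6, 6, 3), c(2.5, 2.5, 1.6))
  n0 <- 0L; n2 <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    z <- array(rnorm(prod(dims)), dims)
    z[blob] <- z[blob] + 3.5          # noisy planted cluster
    f0 <- suppressWarnings(icm_fit(z, mask, mrf_beta = 0))
    f2r <- suppressWarnings(icm_fit(z, mask, mrf_beta = 2))
    n0 <- n0 + isolated_count(threshold_ppm(f0$ppm_act))
    n2 <- n2 + isolated_count(threshold_ppm(f2r$ppm_act))
  }
  expect_lt(n2, n0)
})

test_that("PPM thresholding is strictly greater-than", {
  p <- array(c(0.5, 0.2, 0.8, NA), c(4, 1, 1))
  m <- threshold_ppm(p, 0.5)
  expect_identical(as.logical(m), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(sum(threshold_ppm(array(0, c(2, 2, 2)))), 0)
  p2 <- array(c(0, 0.01, 0.99), c(3, 1, 1))
  expect_equal(sum(threshold_ppm(p2, 0)), 2)
})

test_that("PPM is 0.5 under tied likelihood and prior, ~1 under dominance", {
  dims <- c(3L, 3L, 3L)
  mask <- full_mask(dims)
  labels <- array(1L, dims)
  # center's 6 face neighbors split 3/3 between the two classes
  labels[1, 2, 2] <- 2L; labels[3, 2, 2] <- 2L; labels[2, 1, 2] <- 2L
  fit <- structure(list(K = 2L, means = c(-1, 1), sds = c(0.5, 0.5),
                        mixing = c(0.5, 0.5), signs = c(-1L, 1L),
                        mrf_beta = 0.7, labels = labels, mask = mask),
                   class = "mixture_fit")
  z <- array(0, dims)                # z = 0 equidistant between the classes
  ppm <- compute_ppm(z, fit)
  expect_equal(ppm$ppm_act[2, 2, 1] + ppm$ppm_deact[2, 2, 1], 1)
  # center voxel: 3 neighbors each class, equal likelihood -> exactly 0.5
  expect_equal(ppm$ppm_act[2, 2, 2], 0.5, tolerance = 1e-12)

  # dominance: z at the activated mean, all neighbors activated
  z2 <- array(1, dims)
  lab2 <- array(2L, dims)
  fit2 <- fit; fit2$labels <- lab2; fit2$sds <- c(0.2, 0.2)
  ppm2 <- compute_ppm(z2, fit2)
  expect_gt(ppm2$ppm_act[2, 2, 2], 0.99)
})
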