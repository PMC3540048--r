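rand_vol <- function(dims = c(5L, 4L, 3L), nt = 120L, seed = 1L, tr = 2.5) {
  set.seed(seed)
  volume4d(array(rnorm(prod(dims) * nt), c(dims, nt)), tr_seconds = tr,
           voxel_mm = c(3.5, 3.5, 3.5))
}

# independent oracle: partial correlation from the inverse covariance matrix
# of (x, y, Z) where Z are the non-constant nuisance columns
precision_partial_cor <- function(x, y, Z) {
  Z <- Z[, apply(Z, 2, function(c) sd(c) > 0), drop = FALSE]
  S <- stats::cov(cbind(x, y, Z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

test_that("last window keeps exactly the final frames", {
  v <- rand_vol(nt = 600L, tr = 2.5)
  w <- last_window(v, 5)
  expect_equal(dim(w$data)[4], 120)            # 300 s / 2.5 s
  expect_equal(w$data[, , , 1], v$data[, , , 481])
  expect_equal(w$time_origin_s, 480 * 2.5)
  full <- last_window(v, 25)
  expect_equal(full$data, v$data)
  expect_error(last_window(v, 30), "exceeds")
})

test_that("seed timecourse averages the ROI", {
  v <- rand_vol()
  roi1 <- array(FALSE, dim(v$data)[1:3]); roi1[2, 2, 2] <- TRUE
  expect_equal(seed_timecourse(v, roi1), v$data[2, 2, 2, ])
  roi2 <- roi1; roi2[3, 2, 2] <- TRUE
  v$data[3, 2, 2, ] <- v$data[2, 2, 2, ]
  expect_equal(seed_timecourse(v, roi2), v$data[2, 2, 2, ])
  expect_error(seed_timecourse(v, array(FALSE, dim(v$data)[1:3])), "empty")
})

test_that("partial correlation agrees with two independent formulations", {
  v <- rand_vol(seed = 42)
  dims <- dim(v$data)[1:3]
  nt <- dim(v$data)[4]
  mask <- array(TRUE, dims)
  set.seed(99)
  seed_tc <- rnorm(nt)
  nuis <- cbind(intercept = 1, drift = seq_len(nt) - mean(seq_len(nt)),
                wm = rnorm(nt), csf = rnorm(nt))
  fc <- partial_correlation_map(v, seed_tc, nuis, mask)
  expect_equal(fc$n_nuisance, 4)
  expect_equal(fc$fisher_z, atanh(fc$r))

  qn <- qr(nuis)
  sres <- qr.resid(qn, seed_tc)
  for (i in seq(1, prod(dims), by = 7)) {
    ci <- arrayInd(i, dims)
    y <- v$data[ci[1], ci[2], ci[3], ]
    r_pearson <- cor(sres, qr.resid(qn, y))
    r_prec <- precision_partial_cor(seed_tc, y, nuis)
    expect_equal(fc$r[ci], r_pearson, tolerance = 1e-10)
    expect_equal(fc$r[ci], r_prec, tolerance = 1e-10)
  }
})

test_that("partial correlation edge cases: self, orthogonal, rescaling", {
  v <- rand_vol(seed = 7)
  dims <- dim(v$data)[1:3]
  nt <- dim(v$data)[4]
  mask <- array(TRUE, dims)
  nuis <- cbind(intercept = rep(1, nt), drift = scale(seq_len(nt))[, 1])

  seed_tc <- v$data[1, 1, 1, ]          # voxel equals the seed
  expect_warning(fc <- partial_correlation_map(v, seed_tc, nuis, mask), NA)
  expect_equal(fc$r[1, 1, 1], 1 - 1e-7)
  expect_true(fc$flagged[1, 1, 1])

  # orthogonal voxel residual gives r = 0
  qn <- qr(nuis)
  sres <- qr.resid(qn, seed_tc)
  y_orth <- qr.resid(qr(cbind(nuis, sres)), rnorm(nt))
  v$data[2, 1, 1, ] <- y_orth
  fc2 <- partial_correlation_map(v, seed_tc, nuis, mask)
  expect_equal(fc2$r[2, 1, 1], 0, tolerance = 1e-10)

  # affine rescaling of voxel or seed leaves r unchanged
  v2 <- v; v2$data <- v$data * 3.7 + 11
  fc3 <- partial_correlation_map(v2, 2 * seed_tc - 5, nuis, mask)
  expect_equal(fc3$r, fc2$r, tolerance = 1e-10)

  # a constant voxel has zero-variance residual: flagged, r = 0
  v$data[3, 1, 1, ] <- 4
  expect_warning(fc4 <- partial_correlation_map(v, seed_tc, nuis, mask),
                 "zero-variance")
  expect_equal(fc4$r[3, 1, 1], 0)
  expect_true(fc4$flagged[3, 1, 1])

  expect_error(partial_correlation_map(v, seed_tc, nuis[, -1, drop = FALSE],
                                       mask), "intercept")
})

test_that("fisher z of null partial correlations has variance 1/(n-q-3)", {
  n <- 120L; q <- 3L
  set.seed(123)
  nuis <- cbind(1, scale(seq_len(n))[, 1], rnorm(n), rnorm(n)) # q=3 + int
  qn <- qr(nuis)
  nrep <- 2000L
  X <- qr.resid(qn, matrix(rnorm(n * nrep), n))
  s <- qr.resid(qn, rnorm(n))
  r <- as.numeric(crossprod(s, X)) / (sqrt(sum(s^2)) * sqrt(colSums(X^2)))
  expect_lt(abs(var(atanh(r)) * (n - q - 3) - 1), 0.1)
})

test_that("group FC contrast flags planted coupling and ignores its absence", {
  dims <- c(8L, 8L, 4L)
  mask <- array(TRUE, dims)
  nt <- 120L
  target <- ellipsoid_mask(dims, c(6, 6, 2.5), c(1.6, 1.6, 1.2))
  make_fc <- function(couple, seed) {
    set.seed(seed)
    dat <- array(rnorm(prod(dims) * nt), c(dims, nt))
    seed_tc <- rnorm(nt)
    if (couple) {
      flat <- matrix(dat, ncol = nt)
      flat[which(target), ] <- flat[which(target), ] +
        rep(seed_tc, each = sum(target))
      dat <- array(flat, c(dims, nt))
    }
    v <- volume4d(dat, tr_seconds = 2.5, voxel_mm = c(3.5, 3.5, 3.5))
    nuis <- cbind(intercept = rep(1, nt), drift = scale(seq_len(nt))[, 1])
    partial_correlation_map(v, seed_tc, nuis, mask)
  }
  fc_A <- lapply(1:8, function(s) make_fc(TRUE, 1000 + s))
  fc_B <- lapply(1:8, function(s) make_fc(FALSE, 2000 + s))
  res <- suppressWarnings(group_fc_contrast(fc_A, fc_B, mask))
  expect_gte(dice(res$mask_AgtB, target), 0.6)
  expect_equal(sum(res$mask_BgtA & target), 0)

  # identical condition lists: degenerate z map, empty masks
  res0 <- suppressWarnings(group_fc_contrast(fc_A, fc_A, mask))
  expect_equal(sum(res0$mask_AgtB), 0)
  expect_equal(sum(res0$mask_BgtA), 0)
})
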