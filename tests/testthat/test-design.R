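acq598 <- acquisition_spec(tr_seconds = 2.5, n_volumes = 598)

test_that("infusion EV samples the ramp piecewise-linearly on the clock", {
  ev <- build_infusion_ev(acq598, time_origin_s = 5)
  t <- ev$times
  expect_equal(ev$sampled_ev[t == 540], 0.5)
  expect_equal(ev$sampled_ev[t == 300], 0)
  expect_equal(ev$sampled_ev[t == 780], 1)
  expect_true(all(ev$sampled_ev[t <= 300] == 0))
  expect_true(all(ev$sampled_ev[t >= 780] == 1))
  expect_true(all(diff(ev$sampled_ev) >= 0))
  mid <- t > 300 & t < 780
  expect_equal(ev$sampled_ev[mid], (t[mid] - 300) / 480)

  # frame 200 (0-based) with origin 5 s: t = 505, EV = 205/480
  expect_equal(t[201], 505)
  expect_equal(ev$sampled_ev[201], (505 - 300) / 480)
  expect_equal(ev$sampled_ev[201], 0.4270833, tolerance = 1e-6)

  short <- acquisition_spec(tr_seconds = 2.5, n_volumes = 100)
  expect_error(build_infusion_ev(short), "ramp start")
})

test_that("SVD onset regressors are orthonormal, EV-orthogonal, dominant", {
  ev <- build_infusion_ev(acq598, time_origin_s = 5)
  expect_equal(ncol(build_svd_onset_regressors(ev, k = 0)), 0)

  sv <- build_svd_onset_regressors(ev, k = 3)
  expect_equal(crossprod(sv), diag(3), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(sv, ev$sampled_ev))), 1e-10)
  expect_lt(max(abs(colSums(sv))), 1e-10)

  # oracle: explicit singular spectrum of the residualized shift family
  shifts <- seq(-60, 60, by = 15)
  fam <- vapply(shifts, function(s)
    pmin(1, pmax(0, (ev$times - 300 - s) / 480)), numeric(598))
  B <- cbind(ev$sampled_ev, 1)
  resid <- fam - B %*% solve(crossprod(B), crossprod(B, fam))
  d2 <- svd(resid)$d^2
  expect_gt(d2[1] / sum(d2), 0.80)

  expect_error(build_svd_onset_regressors(ev, onset_shifts_s = c(-15, 0, 15),
                                          k = 3), "smaller")
  # duplicate shifts collapse the family: 0-shift equals the nominal EV, so
  # the residual family has rank 1 and k = 2 must fail
  expect_error(build_svd_onset_regressors(ev, onset_shifts_s = c(0, 0, 15),
                                          k = 2), "rank")
})

test_that("design assembly flags collinear columns and reports conditioning", {
  ev <- build_infusion_ev(acq598, time_origin_s = 5)
  sv <- build_svd_onset_regressors(ev, k = 2)
  set.seed(4)
  wm <- rnorm(598); csf <- rnorm(598)
  X <- suppressMessages(assemble_design(ev, sv, wm, csf))
  expect_equal(colnames(X),
               c("infusion_ev", "svd_1", "svd_2", "drift", "wm", "csf",
                 "intercept"))
  expect_equal(qr(unclass(X))$rank, 7)
  expect_true(is.finite(attr(X, "kappa")))
  expect_message(assemble_design(ev, sv, wm, csf), "condition number")

  expect_error(suppressMessages(assemble_design(ev, sv, wm, wm)), "csf")
  expect_error(suppressMessages(assemble_design(ev, sv, rep(1, 598), csf)),
               "wm")
})

test_that("voxelwise GLM recovers noiseless coefficients exactly", {
  ev <- build_infusion_ev(acq598, time_origin_s = 5)
  sv <- build_svd_onset_regressors(ev, k = 3)
  set.seed(9)
  X <- suppressMessages(assemble_design(ev, sv, rnorm(598), rnorm(598)))

  dims <- c(3L, 2L, 2L)
  nvox <- prod(dims)
  v <- volume4d(aperm(array(3 * ev$sampled_ev + 2, c(598, dims)),
                      c(2, 3, 4, 1)),
                tr_seconds = 2.5, voxel_mm = c(2, 2, 2))
  mask <- array(TRUE, dims)
  fit <- suppressWarnings(fit_voxelwise_glm(v, X, mask))
  expect_equal(as.numeric(fit$amplitude), rep(3, nvox), tolerance = 1e-10)
  expect_equal(fit$dof, 598 - ncol(X))
  # a perfect fit drives t far beyond the clip: z pinned at 8
  expect_true(all(fit$zstat == 8))
})

test_that("amplitude is invariant to orthogonal SVD augmentation", {
  ev <- build_infusion_ev(acq598, time_origin_s = 5)
  set.seed(10)
  wm <- rnorm(598); csf <- rnorm(598)
  X0 <- suppressMessages(assemble_design(ev, NULL, wm, csf))
  X3 <- suppressMessages(assemble_design(
    ev, build_svd_onset_regressors(ev, k = 3), wm, csf))
  y <- 2.5 * ev$sampled_ev + 1   # exact nominal-EV signal, no noise
  b0 <- qr.coef(qr(unclass(X0)), y)[1]
  b3 <- qr.coef(qr(unclass(X3)), y)[1]
  expect_equal(b0, b3, tolerance = 1e-10)
  expect_equal(b0, 2.5, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("t-to-z transform is monotone, odd, and clipped", {
  t <- c(-1e6, -5, -1, -0.2, 0, 0.2, 1, 5, 1e6)
  z <- t_to_z(t, dof = 12)
  expect_equal(z, -rev(z))
  expect_true(all(diff(z) >= 0))
  expect_equal(max(abs(z)), 8)
  expect_equal(t_to_z(0, 5), 0)
  # matched tail probability against direct computation at moderate t
  expect_equal(t_to_z(2.2, 30), qnorm(pt(2.2, 30)), tolerance = 1e-10)
})
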