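#' Infusion explanatory variable
#'
#' The idealized infusion response: 0 during the 5-min baseline, linear ramp
#' from 5 to 13 min, 1 on the plateau. Sampled at the acquisition clock times
#' of the analyzed frames (`time_origin_s` accounts for dropped volumes). No
#' HRF convolution.
#'
#' @param acq an `acquisition_spec`.
#' @param time_origin_s clock time (s) of the first analyzed frame.
#' @param n_volumes number of analyzed frames (defaults to the acquisition's
#'   count; pass the post-drop count when volumes were removed).
#' @param baseline_end_s end of baseline, s (default 300).
#' @param ramp_end_s end of ramp, s (default 780).
#' @return list of class `infusion_design` with `sampled_ev`, `times` and the
#'   breakpoints.
#' @export
build_infusion_ev <- function(acq, time_origin_s = 0,
                              n_volumes = acq$n_volumes,
                              baseline_end_s = 300, ramp_end_s = 780) {
  stopifnot(ramp_end_s > baseline_end_s, n_volumes >= 2)
  times <- time_origin_s + (seq_len(n_volumes) - 1) * acq$tr_seconds
  if (max(times) <= baseline_end_s)
    stop("scan does not cover the ramp start; no infusion response sampled")
  ev <- ramp_fraction(times, 0, baseline_end_s, ramp_end_s)
  structure(list(baseline_end_s = baseline_end_s, ramp_end_s = ramp_end_s,
                 sampled_ev = ev, times = times,
                 tr_seconds = acq$tr_seconds),
            class = "infusion_design")
}

#' SVD onset-nuisance regressors
#'
#' The infusion onset varies with local pharmacodynamics; fitting only the
#' nominal ramp then biases the amplitude. This builds the family of ramps
#' shifted over `onset_shifts_s`, removes each member's projection onto the
#' nominal EV and the intercept, and returns the top-k left singular vectors
#' of the residual family. Including them absorbs onset-shift signal without
#' touching the nominal amplitude (columns are orthonormal and orthogonal to
#' the nominal EV and intercept by construction).
#'
#' @param design an `infusion_design`.
#' @param onset_shifts_s candidate onset shifts, s (default -60..60 by 15).
#' @param k number of components (0 allowed; must be < number of shifts).
#' @return n x k matrix (n x 0 when k = 0).
#' @export
build_svd_onset_regressors <- function(design,
                                       onset_shifts_s = seq(-60, 60, by = 15),
                                       k = 3L) {
  stopifnot(inherits(design, "infusion_design"), k >= 0)
  if (k >= length(onset_shifts_s))
    stop("k must be smaller than the number of onset shifts")
  n <- length(design$sampled_ev)
  if (k == 0L) return(matrix(0, n, 0))
  fam <- vapply(onset_shifts_s, function(s)
    ramp_fraction(design$times, s, design$baseline_end_s, design$ramp_end_s),
    numeric(n))
  B <- cbind(design$sampled_ev, rep(1, n))
  resid <- fam - B %*% solve(crossprod(B), crossprod(B, fam))
  sv <- svd(resid)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank)
    stop(sprintf("k = %d exceeds the numerical rank (%d) of the residual family",
                 k, rank))
  sv$u[, seq_len(k), drop = FALSE]
}

#' Assemble the single-subject design matrix
#'
#' Columns: infusion EV, SVD onset nuisances, mean-centered linear drift,
#' mean-centered WM and CSF timecourses, and an intercept. Rank is checked;
#' a rank-deficient design errors naming the offending columns.
#'
#' @param ev an `infusion_design`.
#' @param svd n x k matrix from [build_svd_onset_regressors()] (or NULL).
#' @param wm_tc,csf_tc nuisance timecourses (covariates of no interest).
#' @return numeric matrix of class `design_matrix` with named columns; the
#'   condition number is attached as attribute `kappa`.
#' @export
assemble_design <- function(ev, svd = NULL, wm_tc, csf_tc) {
  stopifnot(inherits(ev, "infusion_design"))
  n <- length(ev$sampled_ev)
  if (is.null(svd)) svd <- matrix(0, n, 0)
  stopifnot(nrow(svd) == n, length(wm_tc) == n, length(csf_tc) == n)
  drift <- seq_len(n) - (n + 1) / 2
  cols <- cbind(infusion_ev = ev$sampled_ev, svd,
                drift = drift, wm = wm_tc - mean(wm_tc),
                csf = csf_tc - mean(csf_tc), intercept = rep(1, n))
  k <- ncol(svd)
  nm <- c("infusion_ev",
          if (k > 0) paste0("svd_", seq_len(k)),
          "drift", "wm", "csf", "intercept")
  colnames(cols) <- nm
  qrX <- qr(cols)
  if (qrX$rank < ncol(cols)) {
    bad <- character(0)
    kept <- NULL
    for (j in seq_len(ncol(cols))) {
      cand <- cbind(kept, cols[, j])
      if (qr(cand)$rank == ncol(cand)) kept <- cand
      else bad <- c(bad, nm[j])
    }
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  kap <- kappa(cols, exact = TRUE)
  message(sprintf("design matrix: %d rows, %d columns, condition number %.3g",
                  n, ncol(cols), kap))
  structure(cols, kappa = kap, class = c("design_matrix", "matrix"))
}
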