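#' Acquisition parameters
#'
#' Defaults follow a typical 3T gradient-echo EPI infusion protocol:
#' TR 2.5 s, 600 volumes (25 min), 3.5 mm isotropic voxels.
#'
#' @param tr_seconds repetition time, s.
#' @param n_volumes number of acquired volumes.
#' @param voxel_mm length-3 voxel size, mm.
#' @param grid_dims length-3 matrix size of the acquisition grid.
#' @return list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_seconds = 2.5, n_volumes = 600,
                             voxel_mm = c(3.5, 3.5, 3.5),
                             grid_dims = c(20L, 20L, 10L)) {
  stopifnot(tr_seconds > 0, n_volumes >= 1,
            length(voxel_mm) == 3L, all(voxel_mm > 0),
            length(grid_dims) == 3L, all(grid_dims >= 1))
  structure(list(tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
                 voxel_mm = as.numeric(voxel_mm),
                 grid_dims = as.integer(grid_dims)),
            class = "acquisition_spec")
}

#' Synthetic tissue compartments
#'
#' Builds three mutually exclusive masks inside an ellipsoidal "brain":
#' a CSF rim, a GM shell and a WM core, by thresholding the normalized
#' ellipsoidal radius. Stands in for an anatomical segmentation so nuisance
#' extraction and brain masking have something to work on.
#'
#' @param grid_dims length-3 grid size, each at least 8.
#' @return list with logical 3D arrays `gm`, `wm`, `csf` and their union
#'   `brain`.
#' @export
make_tissue_masks <- function(grid_dims) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L)
  if (any(grid_dims < 8L))
    stop("grid too small to host WM/GM/CSF compartments (each dim must be >= 8)")
  semi <- grid_dims / 2 - 0.6
  ctr <- (grid_dims + 1) / 2
  u <- lapply(1:3, function(ax)
    ((seq_len(grid_dims[ax]) - ctr[ax]) / semi[ax])^2)
  r <- sqrt(outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+"))
  brain <- r <= 1
  wm <- r <= 0.55
  gm <- r > 0.55 & r <= 0.8
  csf <- r > 0.8 & r <= 1
  if (!any(wm) || !any(gm) || !any(csf))
    stop("grid too small: an empty tissue compartment resulted")
  list(gm = gm, wm = wm, csf = csf, brain = brain)
}

ramp_fraction <- function(t, onset_shift_s = 0,
                          baseline_end_s = 300, ramp_end_s = 780) {
  pmin(1, pmax(0, (t - baseline_end_s - onset_shift_s) /
                 (ramp_end_s - baseline_end_s)))
}

#' Ground-truth infusion response timecourse
#'
#' The expected drug response is a ramped unit step: flat baseline for the
#' first 5 min, linear ramp from 5 to 13 min, plateau thereafter, scaled by
#' `amplitude` and optionally shifted in onset to emulate subject-specific
#' pharmacodynamics. Not convolved with a hemodynamic response function: the
#' infusion response is far slower than the HRF.
#'
#' @param acq an `acquisition_spec`.
#' @param amplitude response plateau height (signal units).
#' @param onset_shift_s onset shift in seconds, |shift| < 300.
#' @param time_origin_s clock time of the first sample.
#' @return numeric vector of length `acq$n_volumes`.
#' @export
infusion_truth_timecourse <- function(acq, amplitude, onset_shift_s = 0,
                                      time_origin_s = 0) {
  stopifnot(is.finite(amplitude))
  if (abs(onset_shift_s) >= 300)
    stop("|onset_shift_s| must be < 300 s (the baseline length)")
  t <- time_origin_s + (seq_len(acq$n_volumes) - 1) * acq$tr_seconds
  amplitude * ramp_fraction(t, onset_shift_s)
}

#' A planted activation effect
#'
#' @param mask logical 3D array of affected voxels (nonempty).
#' @param amplitude additive plateau amplitude in signal units (sign gives
#'   activation vs deactivation).
#' @param condition which condition carries the effect: "A", "B" or "both".
#' @param onset_jitter_s half-width (s) of the uniform per-session onset
#'   jitter applied to the ramp.
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(mask, amplitude, condition = c("A", "B", "both"),
                           onset_jitter_s = 0) {
  condition <- match.arg(condition)
  stopifnot(is.logical(mask), any(mask), is.finite(amplitude),
            onset_jitter_s >= 0, onset_jitter_s < 300)
  structure(list(mask = mask, amplitude = amplitude, condition = condition,
                 onset_jitter_s = onset_jitter_s),
            class = "planted_effect")
}

#' Ellipsoidal blob mask helper
#'
#' @param grid_dims grid size.
#' @param center voxel-index center (1-based, may be fractional).
#' @param radii length-3 semi-axes in voxels.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(grid_dims, center, radii) {
  idx <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                               y = seq_len(grid_dims[2]),
                               z = seq_len(grid_dims[3])))
  d2 <- ((idx[, 1] - center[1]) / radii[1])^2 +
        ((idx[, 2] - center[2]) / radii[2])^2 +
        ((idx[, 3] - center[3]) / radii[3])^2
  array(d2 <= 1, dim = grid_dims)
}

#' Crossover cohort specification
#'
#' Defines the synthetic study: a 2-condition within-subject crossover where
#' every subject is scanned under both conditions. Voxel series are
#' baseline + planted ramp effects + linear drift + AR(1) WM/CSF nuisance
#' signals (leaking partially into GM) + white Gaussian noise, plus an
#' optional seed-coupled network active only in one condition and only in the
#' steady-state final window.
#'
#' @param n_subjects number of subjects (each scanned in both conditions).
#' @param acquisition an `acquisition_spec`.
#' @param effects list of `planted_effect`s.
#' @param noise_sd per-voxel, per-frame Gaussian noise sd (signal units).
#' @param drift_slope_sd sd of the per-session linear drift, expressed as
#'   total units of drift over the full scan.
#' @param wm_signal,csf_signal lists `(amplitude, ar)` for the AR(1) tissue
#'   nuisance timecourses.
#' @param gm_leak fraction of the WM and CSF nuisance signals added to GM.
#' @param seed_network optional list `(seed_mask, target_mask, amplitude,
#'   condition, window_minutes)`: a shared latent signal added to seed and
#'   target voxels during the final window in the stated condition.
#' @param baseline mean BOLD level, arbitrary units.
#' @param rng_seed integer seed; cohorts are bit-reproducible given the spec.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13,
                        acquisition = acquisition_spec(),
                        effects = list(),
                        noise_sd = 1.0,
                        drift_slope_sd = 0.5,
                        wm_signal = list(amplitude = 2.0, ar = 0.95),
                        csf_signal = list(amplitude = 2.0, ar = 0.95),
                        gm_leak = 0.2,
                        seed_network = NULL,
                        baseline = 1000,
                        rng_seed = 1L) {
  stopifnot(n_subjects >= 1, noise_sd >= 0, drift_slope_sd >= 0,
            gm_leak >= 0, gm_leak <= 1)
  masks <- make_tissue_masks(acquisition$grid_dims)
  for (ef in effects) {
    stopifnot(inherits(ef, "planted_effect"))
    if (any(ef$mask & !masks$brain))
      stop("planted effect mask extends outside the brain ellipsoid")
  }
  if (!is.null(seed_network)) {
    stopifnot(all(c("seed_mask", "target_mask", "amplitude", "condition")
                  %in% names(seed_network)))
    if (is.null(seed_network$window_minutes)) seed_network$window_minutes <- 5
    if (any((seed_network$seed_mask | seed_network$target_mask) & !masks$brain))
      stop("seed-network masks extend outside the brain ellipsoid")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 acquisition = acquisition, effects = effects,
                 noise_sd = noise_sd, drift_slope_sd = drift_slope_sd,
                 wm_signal = wm_signal, csf_signal = csf_signal,
                 gm_leak = gm_leak, seed_network = seed_network,
                 baseline = baseline, rng_seed = as.integer(rng_seed),
                 tissue = masks),
            class = "cohort_spec")
}

subject_stream_seed <- function(rng_seed, subject, condition) {
  cond_i <- match(condition, c("A", "B"))
  as.integer((as.numeric(rng_seed) + 10007 * subject + 101 * cond_i) %%
               (2^31 - 1))
}

ar1_series <- function(n, ar, marginal_sd) {
  innov_sd <- marginal_sd * sqrt(1 - ar^2)
  as.numeric(stats::arima.sim(list(ar = ar), n = n, sd = innov_sd))
}

#' Simulate one subject-session
#'
#' Deterministic given the cohort spec: each (subject, condition) pair uses
#' its own derived RNG substream, so sessions can be generated in any order
#' and still be bit-identical.
#'
#' @param spec a `cohort_spec`.
#' @param subject subject index in 1..n_subjects.
#' @param condition "A" or "B".
#' @return a `volume4d` with background 0 outside the brain.
#' @export
simulate_subject <- function(spec, subject, condition = c("A", "B")) {
  condition <- match.arg(condition)
  stopifnot(subject >= 1, subject <= spec$n_subjects)
  acq <- spec$acquisition
  nt <- acq$n_volumes
  dims <- acq$grid_dims
  msk <- spec$tissue
  brain_idx <- which(msk$brain)
  nvox <- length(brain_idx)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_stream_seed(spec$rng_seed, subject, condition))

  t_s <- (seq_len(nt) - 1) * acq$tr_seconds
  # time x brain-voxel signal matrix
  sig <- matrix(spec$baseline, nrow = nt, ncol = nvox)

  # planted ramp effects with per-session onset jitter
  for (ef in spec$effects) {
    jitter <- if (ef$onset_jitter_s > 0)
      stats::runif(1, -ef$onset_jitter_s, ef$onset_jitter_s) else 0
    if (ef$condition == "both" || ef$condition == condition) {
      tc <- ef$amplitude * ramp_fraction(t_s, jitter)
      cols <- match(which(ef$mask), brain_idx)
      sig[, cols] <- sig[, cols] + tc
    }
  }

  # per-session linear drift across the whole brain
  slope <- stats::rnorm(1, 0, spec$drift_slope_sd)
  drift <- slope * (t_s / max(t_s) - 0.5)
  sig <- sig + drift

  # AR(1) tissue nuisance signals; WM/CSF carry them fully, GM a fraction
  wm_tc <- ar1_series(nt, spec$wm_signal$ar, spec$wm_signal$amplitude)
  csf_tc <- ar1_series(nt, spec$csf_signal$ar, spec$csf_signal$amplitude)
  wm_cols <- match(which(msk$wm), brain_idx)
  csf_cols <- match(which(msk$csf), brain_idx)
  gm_cols <- match(which(msk$gm), brain_idx)
  sig[, wm_cols] <- sig[, wm_cols] + wm_tc
  sig[, csf_cols] <- sig[, csf_cols] + csf_tc
  if (spec$gm_leak > 0)
    sig[, gm_cols] <- sig[, gm_cols] + spec$gm_leak * (wm_tc + csf_tc)

  # seed-coupled network: shared latent only in the final steady-state window
  sn <- spec$seed_network
  if (!is.null(sn) && (sn$condition == "both" || sn$condition == condition)) {
    nwin <- floor(sn$window_minutes * 60 / acq$tr_seconds)
    stopifnot(nwin >= 2, nwin <= nt)
    latent <- stats::rnorm(nwin)
    win <- (nt - nwin + 1):nt
    cols <- match(which(sn$seed_mask | sn$target_mask), brain_idx)
    sig[win, cols] <- sig[win, cols] + sn$amplitude * latent
  }

  if (spec$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(nt * nvox, 0, spec$noise_sd), nt, nvox)

  dat <- array(0, dim = c(dims, nt))
  flat <- matrix(dat, nrow = prod(dims), ncol = nt)
  flat[brain_idx, ] <- t(sig)
  dat <- array(flat, dim = c(dims, nt))
  volume4d(dat, affine = ras_affine(acq$voxel_mm, dims),
           tr_seconds = acq$tr_seconds, time_origin_s = 0)
}

# Save/restore .Random.seed so simulation does not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth maps for a cohort
#'
#' @param spec a `cohort_spec`.
#' @return list with per-condition plateau amplitude maps `amplitude_A`,
#'   `amplitude_B` (zero outside planted masks) and `seed_coupling`, nonzero
#'   on seed-union-target voxels in the coupled condition.
#' @export
cohort_ground_truth <- function(spec) {
  dims <- spec$acquisition$grid_dims
  amp_A <- array(0, dims); amp_B <- array(0, dims)
  for (ef in spec$effects) {
    if (ef$condition %in% c("A", "both")) amp_A[ef$mask] <- amp_A[ef$mask] + ef$amplitude
    if (ef$condition %in% c("B", "both")) amp_B[ef$mask] <- amp_B[ef$mask] + ef$amplitude
  }
  coupling <- array(0, dims)
  sn <- spec$seed_network
  if (!is.null(sn))
    coupling[sn$seed_mask | sn$target_mask] <- sn$amplitude
  list(amplitude_A = amp_A, amplitude_B = amp_B, seed_coupling = coupling)
}

#' Generate a full paired crossover cohort
#'
#' Simulates every (subject, condition) session. With `dir` set, sessions,
#' tissue masks and ground-truth maps are written as NIfTI-1 with a YAML
#' manifest and only file paths are returned; otherwise the `volume4d`
#' objects are kept in memory.
#'
#' @param spec a `cohort_spec`.
#' @param dir optional output directory.
#' @return list with `spec`, `truth`, `tissue` and either `sessions`
#'   (in-memory) or `manifest` (path to YAML).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  truth <- cohort_ground_truth(spec)
  acq <- spec$acquisition
  aff <- ras_affine(acq$voxel_mm, acq$grid_dims)
  if (is.null(dir)) {
    sessions <- list()
    for (s in seq_len(spec$n_subjects))
      for (cond in c("A", "B"))
        sessions[[sprintf("sub%02d_%s", s, cond)]] <-
          simulate_subject(spec, s, cond)
    return(list(spec = spec, truth = truth, tissue = spec$tissue,
                sessions = sessions))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (cond in c("A", "B")) {
      fn <- file.path(dir, sprintf("sub%02d_cond%s_bold.nii.gz", s, cond))
      write_nifti_volume(simulate_subject(spec, s, cond), fn)
      entries[[length(entries) + 1L]] <-
        list(subject = s, condition = cond, bold = basename(fn))
    }
  }
  for (nm in c("gm", "wm", "csf", "brain"))
    write_nifti_volume(array(as.numeric(spec$tissue[[nm]]), acq$grid_dims),
                       file.path(dir, paste0("mask_", nm, ".nii.gz")),
                       affine = aff)
  for (nm in names(truth))
    write_nifti_volume(truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".nii.gz")),
                       affine = aff)
  manifest <- list(
    n_subjects = spec$n_subjects,
    rng_seed = spec$rng_seed,
    baseline = spec$baseline,
    amplitude_units = "absolute additive signal units (baseline 1000)",
    tr_seconds = acq$tr_seconds, n_volumes = acq$n_volumes,
    voxel_mm = acq$voxel_mm, grid_dims = acq$grid_dims,
    sessions = entries,
    masks = as.list(setNames(paste0("mask_", c("gm","wm","csf","brain"), ".nii.gz"),
                             c("gm","wm","csf","brain"))),
    truth = as.list(setNames(paste0("truth_", names(truth), ".nii.gz"),
                             names(truth))))
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  list(spec = spec, truth = truth, tissue = spec$tissue, manifest = mpath)
}
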