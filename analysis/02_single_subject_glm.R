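#!/usr/bin/env Rscript
# Stage 2: preprocessing + single-subject infusion GLM for every session.
#
# Per session: drop the first 2 volumes, smooth at 5 mm FWHM, grand-mean
# normalize to 10000 within the brain, extract WM/CSF nuisance timecourses
# from GM-eroded masks, build the ramped infusion EV with k = 3 SVD
# onset-nuisance regressors, and fit the voxelwise GLM. Amplitude and z maps
# are written per session; one design matrix is exported as TSV for audit.

library(phmri)

cohort_dir <- "results/cohort"
out_dir <- "results/glm"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- phmri_config(rng_seed = 7L)

man <- yaml::read_yaml(file.path(cohort_dir, "manifest.yaml"))
tissue <- list(
  gm = read_nifti_volume(file.path(cohort_dir, man$masks$gm)) > 0.5,
  wm = read_nifti_volume(file.path(cohort_dir, man$masks$wm)) > 0.5,
  csf = read_nifti_volume(file.path(cohort_dir, man$masks$csf)) > 0.5,
  brain = read_nifti_volume(file.path(cohort_dir, man$masks$brain)) > 0.5)

first <- TRUE
for (sess in man$sessions) {
  vol <- read_nifti_volume(file.path(cohort_dir, sess$bold))
  vol <- phmri:::preprocess_session(vol, tissue, cfg)
  glm <- suppressWarnings(phmri:::glm_session(vol, tissue, cfg))
  stem <- sprintf("sub%02d_cond%s", sess$subject, sess$condition)
  aff <- vol$affine
  amp <- glm$amplitude; amp[is.na(amp)] <- 0
  zst <- glm$zstat; zst[is.na(zst)] <- 0
  write_nifti_volume(amp, file.path(out_dir, paste0(stem, "_amplitude.nii.gz")),
                     affine = aff)
  write_nifti_volume(zst, file.path(out_dir, paste0(stem, "_zstat.nii.gz")),
                     affine = aff)
  if (first) {
    ev <- build_infusion_ev(acquisition_spec(vol$tr_seconds,
                                             dim(vol$data)[4]),
                            time_origin_s = vol$time_origin_s)
    nm <- nuisance_extraction_masks(tissue)
    X <- assemble_design(ev, build_svd_onset_regressors(ev, cfg$glm$svd_shifts_s,
                                                        cfg$glm$svd_k),
                         mean_timecourse(vol, nm$wm),
                         mean_timecourse(vol, nm$csf))
    write_design_tsv(X, file.path(out_dir, "design_matrix_example.tsv"))
    first <- FALSE
  }
  cat(sprintf("%s: dof %d, amplitude range [%.3g, %.3g]\n",
              stem, glm$dof, min(amp[tissue$brain]), max(amp[tissue$brain])))
}
cat("amplitude and z maps in ", out_dir, "\n", sep = "")
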