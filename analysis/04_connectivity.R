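#!/usr/bin/env Rscript
# Stage 4: seed-based partial-correlation connectivity on the final 5 min.
#
# Per session: window the preprocessed data to the last 5 minutes (steady
# state), extract the seed mean timecourse, and map the partial correlation
# of every brain voxel with the seed given intercept, within-window linear
# drift, and WM/CSF timecourses. Fisher-z maps enter the paired group
# contrast and mixture inference as in stage 3.

library(phmri)

cohort_dir <- "results/cohort"
out_dir <- "results/fc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- phmri_config(rng_seed = 7L)

man <- yaml::read_yaml(file.path(cohort_dir, "manifest.yaml"))
tissue <- list(
  gm = read_nifti_volume(file.path(cohort_dir, man$masks$gm)) > 0.5,
  wm = read_nifti_volume(file.path(cohort_dir, man$masks$wm)) > 0.5,
  csf = read_nifti_volume(file.path(cohort_dir, man$masks$csf)) > 0.5,
  brain = read_nifti_volume(file.path(cohort_dir, man$masks$brain)) > 0.5)
geom <- default_phantom_geometry(unlist(man$grid_dims))

fc_A <- list(); fc_B <- list()
for (sess in man$sessions) {
  vol <- read_nifti_volume(file.path(cohort_dir, sess$bold))
  vol <- phmri:::preprocess_session(vol, tissue, cfg)
  fc <- suppressWarnings(phmri:::fc_session(vol, tissue, geom$seed, cfg))
  if (sess$condition == "A") fc_A[[sess$subject]] <- fc
  else fc_B[[sess$subject]] <- fc
}
cat(sprintf("fc maps: %d frames, %d nuisance regressors per session\n",
            fc_A[[1]]$n_timepoints, fc_A[[1]]$n_nuisance))

res <- suppressWarnings(group_fc_contrast(fc_A, fc_B, tissue$brain,
                                          ppm_threshold = cfg$ppm$threshold,
                                          mrf_beta = cfg$ppm$mrf_beta))
aff <- ras_affine(unlist(man$voxel_mm), unlist(man$grid_dims))
tab <- label_clusters(res$mask_AgtB, res$group$zstat_AgtB, aff)
write_cluster_table(tab, file.path(out_dir, "fc_clusters.tsv"))
z <- res$group$zstat_AgtB; z[is.na(z)] <- 0
write_nifti_volume(z, file.path(out_dir, "fc_zstat_AgtB.nii.gz"), affine = aff)

coupled <- read_nifti_volume(file.path(cohort_dir, man$truth$seed_coupling)) > 0
cat(sprintf("A>B connectivity: %d voxels, Dice vs seed+target %.3f\n",
            sum(res$mask_AgtB), dice(res$mask_AgtB, coupled)))
cat(sprintf("B>A connectivity: %d voxels\n", sum(res$mask_BgtA)))
cat("tables in ", out_dir, "\n", sep = "")
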