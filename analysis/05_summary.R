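#!/usr/bin/env Rscript
# Stage 5: collate the cluster tables and summarize recovery.

library(phmri)

contrast <- read_cluster_table("results/group/contrast_clusters.tsv")
fc <- read_cluster_table("results/fc/fc_clusters.tsv")

cat("== infusion contrast clusters (A>B first, then B>A) ==\n")
print(contrast, row.names = FALSE)
cat(sprintf("\ntotal suprathreshold volume: %.3f cm^3 in %d cluster(s)\n",
            sum(contrast$volume_cm3), nrow(contrast)))

cat("\n== connectivity-difference clusters (A>B) ==\n")
print(fc, row.names = FALSE)

cat("\nLaterality: R/L = peak beyond +/-2 mm of the midline, B = within.\n")
cat("Volumes are voxel count x voxel volume; peaks are max-|z| voxels.\n")
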