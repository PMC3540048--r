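#' Cluster volume in cubic centimeters
#'
#' @param n_voxels voxel count (>= 0).
#' @param voxel_mm length-3 voxel size, mm.
#' @return `n_voxels * prod(voxel_mm) / 1000`, exactly.
#' @export
cluster_volume <- function(n_voxels, voxel_mm) {
  stopifnot(n_voxels >= 0, length(voxel_mm) == 3L, all(voxel_mm > 0))
  n_voxels * prod(voxel_mm) / 1000
}

connectivity_offsets <- function(connectivity = c(26, 6, 18)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]),
                                       c("26", "6", "18")))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  offs[keep, , drop = FALSE]
}

# connected components by breadth-first search; seeds visited in ascending
# linear order so labels are deterministic and traversal-order independent
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  lab <- array(0L, dims)
  idx <- which(mask)
  comp <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    queue <- seed
    lab[seed] <- comp
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      cc <- arrayInd(cur, dims)
      for (j in seq_len(nrow(offs))) {
        nc <- sweep(cc, 2L, offs[j, ], "+")
        ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
              nc[, 2] >= 1 & nc[, 2] <= dims[2] &
              nc[, 3] >= 1 & nc[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * dims[1] +
          (nc[ok, 3] - 1L) * dims[1] * dims[2]
        new <- lin[mask[lin] & lab[lin] == 0L]
        if (length(new)) {
          lab[new] <- comp
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Cluster table from a suprathreshold mask
#'
#' Splits the mask into connected components and summarizes each the way
#' activation tables are reported: laterality of the peak, peak z, peak world
#' coordinates (mm), voxel count and volume in cm^3. The peak is the voxel
#' maximizing |z| (ties broken by lowest linear index); laterality comes from
#' the peak's world x: beyond +2 mm is R, beyond -2 mm is L, the midline band
#' is B. The record's sign is "increased" for a positive peak z, "decreased"
#' otherwise.
#'
#' @param mask logical 3D suprathreshold mask.
#' @param zmap 3D statistic map on the same grid.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param connectivity 26 (default), 18 or 6.
#' @param midline_mm half-width of the bilateral band (default 2).
#' @return data.frame with one row per cluster: `cluster_id`, `laterality`,
#'   `peak_z`, `x`, `y`, `z`, `n_voxels`, `volume_cm3`, `sign`. Empty mask
#'   gives zero rows.
#' @export
label_clusters <- function(mask, zmap, affine, connectivity = 26,
                           midline_mm = 2) {
  stopifnot(all(dim(mask) == dim(zmap)))
  empty <- data.frame(cluster_id = integer(0), laterality = character(0),
                      peak_z = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_voxels = integer(0),
                      volume_cm3 = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  lab <- label_components(mask, connectivity)
  vm <- voxel_dims(affine)
  recs <- lapply(seq_len(max(lab)), function(cid) {
    vox <- which(lab == cid)
    zv <- zmap[vox]
    peak <- vox[which.max(abs(zv))]      # which.max: first max = lowest index
    pz <- zmap[peak]
    ci <- arrayInd(peak, dim(mask))
    world <- as.numeric(affine %*% c(ci - 1L, 1))[1:3]
    latr <- if (world[1] > midline_mm) "R"
            else if (world[1] < -midline_mm) "L" else "B"
    data.frame(cluster_id = cid, laterality = latr, peak_z = pz,
               x = world[1], y = world[2], z = world[3],
               n_voxels = length(vox),
               volume_cm3 = cluster_volume(length(vox), vm),
               sign = if (pz >= 0) "increased" else "decreased",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a cluster table as TSV
#'
#' Rows are ordered "increased" before "decreased", then by world y
#' descending, matching the convention of published activation tables.
#'
#' @param records data.frame from [label_clusters()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(records, path) {
  ord <- order(match(records$sign, c("increased", "decreased")),
               -records$y)
  utils::write.table(records[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a cluster table
#' @param path TSV path written by [write_cluster_table()].
#' @return data.frame.
#' @export
read_cluster_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(cluster_id = "integer",
                                   laterality = "character",
                                   peak_z = "numeric", x = "numeric",
                                   y = "numeric", z = "numeric",
                                   n_voxels = "integer",
                                   volume_cm3 = "numeric",
                                   sign = "character"),
                    stringsAsFactors = FALSE)
}
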