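#' Paired group-level contrast
#'
#' Classical paired t test per voxel on per-subject statistic maps from a
#' crossover: d_i = A_i - B_i, t = mean(d) / (sd(d) / sqrt(n)), dof = n - 1,
#' transformed to z by matched quantiles. Both contrast directions are
#' returned; they are exact negations of each other.
#'
#' @param amps_A,amps_B equal-length lists of 3D maps (one per subject),
#'   pairing by position.
#' @param mask logical 3D analysis mask; voxels that are NA in any subject
#'   are dropped from it.
#' @return list of class `paired_group` with `mean_diff`, `zstat_AgtB`,
#'   `zstat_BgtA`, `tstat`, `n_pairs`, `dof` and the effective `mask`.
#' @export
paired_contrast <- function(amps_A, amps_B, mask) {
  n <- length(amps_A)
  if (length(amps_B) != n) stop("condition lists must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  dims <- dim(mask)
  for (m in c(amps_A, amps_B))
    if (!all(dim(m) == dims)) stop("all maps must share the mask grid")

  A <- vapply(amps_A, function(m) as.numeric(m), numeric(prod(dims)))
  B <- vapply(amps_B, function(m) as.numeric(m), numeric(prod(dims)))
  D <- A - B                                  # voxel x subject
  ok <- as.logical(mask) & rowSums(is.na(D)) == 0L
  idx <- which(ok)
  d <- D[idx, , drop = FALSE]

  md <- rowMeans(d)
  sdd <- apply(d, 1L, stats::sd)
  dof <- n - 1L
  t <- numeric(length(idx))
  pos <- sdd > 0
  t[pos] <- md[pos] / (sdd[pos] / sqrt(n))
  z <- t_to_z(t, dof)
  if (any(!pos)) {
    degen <- !pos & md != 0
    if (any(degen)) {
      warning(sprintf(
        "%d voxel(s) with zero paired-difference sd; z set to sign(mean) * 8",
        sum(degen)))
      z[degen] <- sign(md[degen]) * 8
    }
    z[!pos & md == 0] <- 0
  }

  to_map <- function(v) {
    m <- array(NA_real_, dims); m[idx] <- v; m
  }
  eff_mask <- array(FALSE, dims); eff_mask[idx] <- TRUE
  structure(list(mean_diff = to_map(md), tstat = to_map(t),
                 zstat_AgtB = to_map(z), zstat_BgtA = to_map(-z),
                 n_pairs = n, dof = dof, mask = eff_mask),
            class = "paired_group")
}
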