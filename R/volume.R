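#' 4D BOLD volume container
#'
#' A `volume4d` bundles a 4D array indexed (x, y, z, t) with its voxel-to-world
#' affine (RAS+, mm) and the repetition time. The time origin records where
#' frame 1 sits on the acquisition clock, so that dropping initial volumes
#' shifts subsequent design-matrix sampling correctly.
#'
#' @param data 4D numeric array, all values finite, at least 2 timepoints.
#' @param affine 4x4 voxel-to-world transform in mm. If `NULL`, an RAS+ affine
#'   with isocenter origin is built from `voxel_mm`.
#' @param tr_seconds repetition time in seconds.
#' @param voxel_mm length-3 voxel size in mm, used only when `affine` is NULL.
#' @param time_origin_s acquisition time (s) of the first retained frame.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine = NULL, tr_seconds,
                     voxel_mm = c(3.5, 3.5, 3.5), time_origin_s = 0) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("volume4d needs at least 2 timepoints")
  if (!all(is.finite(data)))
    stop("volume4d data must be finite everywhere")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive number")
  if (is.null(affine))
    affine <- ras_affine(voxel_mm, dim(data)[1:3])
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(data = data, affine = affine,
                 tr_seconds = as.numeric(tr_seconds),
                 time_origin_s = as.numeric(time_origin_s)),
            class = "volume4d")
}

#' RAS+ affine with isocenter origin
#'
#' Diagonal scaling by voxel size, translated so the grid center maps to
#' world (0, 0, 0). Voxel indices are 0-based in world-coordinate
#' computations, matching the NIfTI convention.
#'
#' @param voxel_mm length-3 positive voxel dimensions (mm).
#' @param grid_dims length-3 grid size.
#' @return 4x4 affine matrix.
#' @export
ras_affine <- function(voxel_mm, grid_dims) {
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0),
            length(grid_dims) == 3L, all(grid_dims >= 1))
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -(grid_dims - 1) / 2 * voxel_mm
  aff
}

#' Voxel dimensions from an affine
#' @param affine 4x4 voxel-to-world matrix.
#' @return length-3 voxel sizes in mm (column norms).
#' @export
voxel_dims <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

n_timepoints <- function(vol) dim(vol$data)[4]

#' Acquisition clock times of each retained frame
#' @param vol a `volume4d`.
#' @return numeric vector, seconds.
#' @export
frame_times <- function(vol) {
  vol$time_origin_s + (seq_len(n_timepoints(vol)) - 1) * vol$tr_seconds
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d frames, TR %.3g s, t0 %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, x$time_origin_s))
  invisible(x)
}

#' Write a 4D volume (or 3D map) as NIfTI-1
#'
#' @param vol a `volume4d`, or a 3D/4D numeric array when `affine` is given.
#' @param path output path, conventionally ending in `.nii.gz`.
#' @param affine affine override for bare arrays.
#' @param tr_seconds TR override for bare arrays.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, affine = NULL, tr_seconds = 1) {
  if (inherits(vol, "volume4d")) {
    arr <- vol$data; affine <- vol$affine; tr_seconds <- vol$tr_seconds
  } else {
    arr <- vol
    if (is.null(affine)) stop("bare arrays need an explicit `affine`")
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  vd <- voxel_dims(affine)
  RNifti::pixdim(img) <- c(vd, tr_seconds)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a `volume4d` (4D) or plain array (3D)
#'
#' @param path NIfTI file path.
#' @param time_origin_s acquisition time of the first stored frame.
#' @return `volume4d` for 4D images, otherwise an array with an `affine`
#'   attribute.
#' @export
read_nifti_volume <- function(path, time_origin_s = 0) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L) {
    tr <- RNifti::pixdim(img)[4]
    volume4d(arr, affine = aff, tr_seconds = tr, time_origin_s = time_origin_s)
  } else {
    attr(arr, "affine") <- aff
    arr
  }
}
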