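#' 3D fluorescence volume with physical voxel size
#'
#' @param voxels 3D numeric array of intensities (x, y, z order; x is the
#'   cell's long axis by convention).
#' @param voxel_size Numeric length-3 vector, micrometres per voxel along
#'   each axis.
#' @param channel Channel name (e.g. `"di8anepps"`, `"mtg"`, `"tmrm"`).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size, channel = "unknown") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  voxel_size <- as.numeric(voxel_size)
  abort_if(length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
             any(voxel_size <= 0), "voxel_size must be 3 positive numbers")
  abort_if(any(!is.finite(voxels)), "voxel intensities must be finite")
  structure(list(voxels = voxels, voxel_size = voxel_size, channel = channel),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %s, %dx%dx%d voxels @ %.3g x %.3g x %.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Binary masks derived from a volume
#'
#' Bundles the cell mask with the t-tubule mask and (optionally) its skeleton.
#' Invariants `tats_mask` within `cell_mask` and `skeleton_mask` within
#' `tats_mask` are enforced.
#'
#' @param cell_mask,tats_mask,skeleton_mask Logical 3D arrays of equal
#'   dimension (`skeleton_mask` may be `NULL`).
#' @param voxel_size Micrometres per voxel along each axis.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(cell_mask, tats_mask, skeleton_mask = NULL,
                           voxel_size) {
  stopifnot(is.array(cell_mask), is.array(tats_mask))
  abort_if(!identical(dim(cell_mask), dim(tats_mask)),
           "cell_mask and tats_mask dimensions differ")
  cell_mask <- cell_mask > 0
  tats_mask <- tats_mask > 0
  abort_if(any(tats_mask & !cell_mask), "tats_mask must lie within cell_mask")
  if (!is.null(skeleton_mask)) {
    skeleton_mask <- skeleton_mask > 0
    abort_if(!identical(dim(skeleton_mask), dim(cell_mask)),
             "skeleton_mask dimensions differ")
    abort_if(any(skeleton_mask & !tats_mask),
             "skeleton_mask must lie within tats_mask")
  }
  structure(list(cell_mask = cell_mask, tats_mask = tats_mask,
                 skeleton_mask = skeleton_mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "labeled_volume")
}

#' Write a volume as multi-page TIFF plus a YAML voxel-size sidecar
#'
#' Intensities are stored as 32-bit floats scaled to `[0, 1]`; the scale
#' factor and voxel size go to `<path>.yaml` so round trips are exact up to
#' float precision.
#'
#' @param vol A [volume_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  v <- vol$voxels
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) (t(v[, , k]) - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(voxel_size_xyz_um = as.numeric(vol$voxel_size),
                        channel = vol$channel,
                        intensity_offset = lo, intensity_scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; the sidecar `<path>.yaml` must exist (the voxel
#'   size is never silently defaulted).
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".yaml")
  abort_if(!file.exists(sidecar),
           "voxel-size sidecar '%s' is missing; refusing to guess", sidecar)
  meta <- yaml::read_yaml(sidecar)
  abort_if(is.null(meta$voxel_size_xyz_um),
           "sidecar '%s' lacks voxel_size_xyz_um", sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  v <- array(0, dim = c(d[2], d[1], nz))
  for (k in seq_len(nz)) v[, , k] <- t(pages[[k]])
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% 1
  volume_image(v * sc + off, meta$voxel_size_xyz_um,
               meta$channel %||% "unknown")
}
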