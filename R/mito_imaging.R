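#' Cell mask from cytosolic autofluorescence
#'
#' Same machinery as [segment_cell()]: the low cytosolic background of the
#' dye channel (or a dedicated autofluorescence channel) is smoothed,
#' thresholded (Otsu), reduced to the largest connected component and
#' hole-filled per slice.
#'
#' @param image A [volume_image()]; by default the MTG channel's cytosolic
#'   background serves as the autofluorescence signal.
#' @param smooth_sigma_um Smoothing sigma, um.
#' @return Logical 3D cell mask.
#' @export
mask_cell_autofluorescence <- function(image, smooth_sigma_um = 0.5) {
  segment_cell(image, smooth_sigma_um)
}

#' Mode + 2 SD mitochondrial threshold
#'
#' The histogram mode of the within-cell intensities (256 bins over the
#' within-cell range, ties toward the lower bin) plus twice the SD of the
#' raw within-cell intensities. Voxels above the threshold inside the cell
#' mask form the mitochondrial mask; their share of the cell volume is the
#' mitochondrial density.
#'
#' @param channel A [volume_image()] (typically MTG).
#' @param cell_mask Logical cell mask.
#' @param n_bins Histogram bins for the mode.
#' @return List: `mito_mask`, `threshold`, `mode`, `sd`, `density_pct`.
#' @export
threshold_mito <- function(channel, cell_mask, n_bins = 256L) {
  stopifnot(inherits(channel, "volume_image"))
  abort_if(!any(cell_mask), "empty cell mask")
  vals <- channel$voxels[cell_mask]
  rng <- range(vals)
  abort_if(rng[1] == rng[2], "degenerate (constant) within-mask intensities")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(vals, breaks, all.inside = TRUE), n_bins)
  k <- which.max(counts)   # which.max takes the first (lower) bin on ties
  mode_val <- (breaks[k] + breaks[k + 1L]) / 2
  s <- stats::sd(vals)
  thr <- mode_val + 2 * s
  mito <- cell_mask & channel$voxels > thr
  list(mito_mask = mito, threshold = thr, mode = mode_val, sd = s,
       density_pct = 100 * sum(mito) / sum(cell_mask))
}

#' TMRM/MTG summed-signal ratio within the cell
#'
#' The sum of the TMRM signal over the cell mask divided by the sum of the
#' MTG signal over the same mask; the study's indicator of mitochondrial
#' inner-membrane potential.
#'
#' @param tmrm,mtg [volume_image()] channels.
#' @param cell_mask Logical cell mask.
#' @return Dimensionless ratio.
#' @export
channel_ratio <- function(tmrm, mtg, cell_mask) {
  stopifnot(inherits(tmrm, "volume_image"), inherits(mtg, "volume_image"))
  denom <- sum(mtg$voxels[cell_mask])
  abort_if(denom == 0, "MTG sum within the mask is zero: ratio undefined")
  sum(tmrm$voxels[cell_mask]) / denom
}

#' Voxel-wise Pearson colocalization of two channels
#'
#' @param ch1,ch2 [volume_image()] channels.
#' @param cell_mask Logical cell mask restricting the comparison.
#' @return Pearson correlation coefficient.
#' @export
colocalization_pearson <- function(ch1, ch2, cell_mask) {
  stopifnot(inherits(ch1, "volume_image"), inherits(ch2, "volume_image"))
  abort_if(sum(cell_mask) < 3, "mask too small for a correlation")
  stats::cor(ch1$voxels[cell_mask], ch2$voxels[cell_mask])
}

#' All mitochondrial metrics for one cell
#'
#' Cell masking from autofluorescence (MTG background), mode + 2 SD
#' mitochondrial thresholding on MTG, mean channel intensities within the
#' cell, the TMRM/MTG summed-signal ratio, and Pearson colocalization.
#'
#' @param mtg,tmrm [volume_image()] channels.
#' @param cell_mask Optional precomputed cell mask; derived from MTG
#'   autofluorescence when `NULL`.
#' @return One-row data frame: `mito_volume_fraction_pct`, `mean_mtg`,
#'   `mean_tmrm`, `tmrm_mtg_ratio`, `pearson_r`.
#' @export
mito_metrics <- function(mtg, tmrm, cell_mask = NULL) {
  if (is.null(cell_mask)) cell_mask <- mask_cell_autofluorescence(mtg)
  thr <- threshold_mito(mtg, cell_mask)
  data.frame(mito_volume_fraction_pct = thr$density_pct,
             mean_mtg = mean(mtg$voxels[cell_mask]),
             mean_tmrm = mean(tmrm$voxels[cell_mask]),
             tmrm_mtg_ratio = channel_ratio(tmrm, mtg, cell_mask),
             pearson_r = colocalization_pearson(tmrm, mtg, cell_mask))
}
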