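#' Specification for a t-tubule lattice phantom
#'
#' A box-shaped cell containing a sarcomeric lattice of transverse tubules:
#' line elements along y placed on a (x, z) grid at `transverse_spacing`,
#' jittered, randomly dropped out, and optionally connected by axial
#' elements along x. The rendered image is the tubule mask plus a surface
#' membrane shell, blurred by a Gaussian PSF and noised; the pre-blur tubule
#' mask is retained as ground truth.
#'
#' @param cell_extent Cell size in um (x = long axis, y, z).
#' @param voxel_size um per voxel per axis.
#' @param transverse_spacing Lattice spacing in x and z, um; must exceed
#'   twice the tubule radius.
#' @param tubule_radius Tubule radius, um.
#' @param axial_element_prob Probability of an axial connector per lattice
#'   gap.
#' @param dropout_prob Probability that a transverse element is missing.
#' @param position_jitter_sd SD of element position jitter, um.
#' @param psf_sigma Gaussian PSF sigma per axis, um.
#' @param noise_sd Additive Gaussian image noise (contrast units; tubule
#'   contrast is 1).
#' @param background Background intensity.
#' @param margin_um Empty margin around the cell, um.
#' @param seed RNG seed.
#' @return A `tats_phantom_spec` list.
#' @export
tats_phantom_spec <- function(cell_extent = c(40, 16, 8),
                              voxel_size = c(0.25, 0.25, 0.5),
                              transverse_spacing = 2.0,
                              tubule_radius = 0.3,
                              axial_element_prob = 0.3,
                              dropout_prob = 0.1,
                              position_jitter_sd = 0.08,
                              psf_sigma = c(0.11, 0.11, 0.30),
                              noise_sd = 0.02,
                              background = 0.2,
                              margin_um = 2,
                              seed = 1L) {
  abort_if(transverse_spacing <= 2 * tubule_radius,
           "transverse_spacing must exceed twice the tubule radius")
  for (p in c(axial_element_prob, dropout_prob)) {
    abort_if(p < 0 || p > 1, "probabilities must be in [0, 1]")
  }
  if (length(psf_sigma) == 1L) psf_sigma <- rep(psf_sigma, 3)
  structure(list(cell_extent = cell_extent, voxel_size = voxel_size,
                 transverse_spacing = transverse_spacing,
                 tubule_radius = tubule_radius,
                 axial_element_prob = axial_element_prob,
                 dropout_prob = dropout_prob,
                 position_jitter_sd = position_jitter_sd,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 background = background, margin_um = margin_um,
                 seed = seed),
            class = "tats_phantom_spec")
}

#' Generate a t-tubule phantom volume with ground truth
#'
#' @param spec A [tats_phantom_spec()].
#' @return List: `image` (a [volume_image()]), `truth` (list with
#'   `cell_mask`, `tats_mask`, `analytic_volume_fraction_pct` from the
#'   cylinder geometry, element counts and the spacing).
#' @export
gen_tats_volume <- function(spec) {
  stopifnot(inherits(spec, "tats_phantom_spec"))
  vs <- spec$voxel_size
  ext <- spec$cell_extent + 2 * spec$margin_um
  dims <- pmax(4L, round(ext / vs))
  # physical voxel-centre coordinates
  cx <- (seq_len(dims[1]) - 0.5) * vs[1]
  cy <- (seq_len(dims[2]) - 0.5) * vs[2]
  cz <- (seq_len(dims[3]) - 0.5) * vs[3]
  lo <- rep(spec$margin_um, 3)
  hi <- lo + spec$cell_extent
  cell <- array(FALSE, dims)
  ix <- which(cx >= lo[1] & cx <= hi[1])
  iy <- which(cy >= lo[2] & cy <= hi[2])
  iz <- which(cz >= lo[3] & cz <= hi[3])
  cell[ix, iy, iz] <- TRUE

  with_seed(spec$seed, {
    s <- spec$transverse_spacing
    # interior lattice positions (keep one radius clear of the cell surface)
    gx <- seq(lo[1] + s / 2, hi[1] - s / 2, by = s)
    gz <- seq(lo[3] + s / 2, hi[3] - s / 2, by = s)
    y0 <- lo[2] + spec$tubule_radius
    y1 <- hi[2] - spec$tubule_radius
    centre <- array(FALSE, dims)
    n_trans <- 0L
    kept <- matrix(FALSE, length(gx), length(gz))
    for (i in seq_along(gx)) for (j in seq_along(gz)) {
      if (stats::runif(1) < spec$dropout_prob) next
      kept[i, j] <- TRUE
      n_trans <- n_trans + 1L
      x <- gx[i] + stats::rnorm(1, 0, spec$position_jitter_sd)
      z <- gz[j] + stats::rnorm(1, 0, spec$position_jitter_sd)
      xi <- which.min(abs(cx - x)); zi <- which.min(abs(cz - z))
      yi <- which(cy >= y0 & cy <= y1)
      centre[xi, yi, zi] <- TRUE
    }
    n_axial <- 0L
    axial_len_um <- 0
    if (length(gx) > 1) {
      for (i in seq_len(length(gx) - 1)) for (j in seq_along(gz)) {
        if (kept[i, j] && kept[i + 1, j] &&
            stats::runif(1) < spec$axial_element_prob) {
          n_axial <- n_axial + 1L
          y <- stats::runif(1, y0, y1)
          z <- gz[j] + stats::rnorm(1, 0, spec$position_jitter_sd)
          yi <- which.min(abs(cy - y)); zi <- which.min(abs(cz - z))
          xi <- which(cx >= gx[i] & cx <= gx[i + 1])
          centre[xi, yi, zi] <- TRUE
          axial_len_um <- axial_len_um + s
        }
      }
    }

    tats <- array(FALSE, dims)
    if (any(centre)) {
      dist <- distance_transform(centre, vs)
      tats <- dist <= spec$tubule_radius & cell
    }

    # surface membrane shell (one erosion step thick); the cell interior
    # carries a uniform dye/autofluorescence base so cell segmentation has
    # an interior signal to work with, as in real Di-8-ANEPPS stacks
    shell <- cell & !erode6(cell)
    img <- spec$background * cell + 1.0 * (tats | shell)
    img <- blur3d(img, spec$psf_sigma / vs)
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
    }

    cell_vol <- prod(spec$cell_extent)
    tub_len <- n_trans * (y1 - y0) + axial_len_um
    analytic_pct <- 100 * pi * spec$tubule_radius^2 * tub_len / cell_vol
    list(image = volume_image(img, vs, "di8anepps"),
         truth = list(cell_mask = cell, tats_mask = tats,
                      analytic_volume_fraction_pct = analytic_pct,
                      n_transverse = n_trans, n_axial = n_axial,
                      transverse_spacing = s))
  })
}

#' Specification for a dual-channel mitochondrial phantom
#'
#' A box cell with cytosolic autofluorescence containing a mitochondrial
#' compartment occupying `mito_volume_fraction` of the cell volume (a
#' smoothed random field cut at the matching quantile). Both channels share
#' the compartment structure; independent per-channel noise is scaled so the
#' within-cell Pearson correlation between the channels hits
#' `target_channel_correlation` in expectation (noise SD can be overridden,
#' in which case the realized correlation simply follows from it).
#'
#' @param cell_extent,voxel_size,margin_um Cell geometry as in
#'   [tats_phantom_spec()].
#' @param mito_volume_fraction Fraction of cell volume that is
#'   mitochondrial.
#' @param target_channel_correlation Pearson r aimed for between the two
#'   channels within the cell mask.
#' @param channel_means Named mean in-mitochondria intensities,
#'   `c(mtg = , tmrm = )`.
#' @param noise_sd Optional per-channel noise SD override (intensity units).
#' @param texture_sigma_um Smoothing of the compartment field, um.
#' @param seed RNG seed.
#' @return A `mito_phantom_spec` list.
#' @export
mito_phantom_spec <- function(cell_extent = c(40, 16, 8),
                              voxel_size = c(0.25, 0.25, 0.4),
                              mito_volume_fraction = 0.30,
                              target_channel_correlation = 0.7,
                              channel_means = c(mtg = 100, tmrm = 80),
                              noise_sd = NULL,
                              texture_sigma_um = 0.5,
                              margin_um = 2,
                              seed = 1L) {
  abort_if(mito_volume_fraction <= 0 || mito_volume_fraction >= 1,
           "mito_volume_fraction must be in (0, 1)")
  r <- target_channel_correlation
  abort_if(r <= 0 || r > 1, "target correlation must be in (0, 1]")
  structure(list(cell_extent = cell_extent, voxel_size = voxel_size,
                 mito_volume_fraction = mito_volume_fraction,
                 target_channel_correlation = r,
                 channel_means = channel_means, noise_sd = noise_sd,
                 texture_sigma_um = texture_sigma_um, margin_um = margin_um,
                 seed = seed),
            class = "mito_phantom_spec")
}

#' Generate a dual-channel mitochondrial phantom with ground truth
#'
#' Channel model within the cell: `base + amplitude * M + noise`, where `M`
#' is the mitochondrial indicator and `base = 0.1 * channel_mean` provides
#' the cytosolic autofluorescence used for cell masking. With the indicator
#' variance `f (1 - f)` shared between channels, independent noise of
#' relative SD `sqrt(f (1 - f) (1 - r) / r)` yields channel correlation `r`;
#' at a target of exactly 1 the channels are exactly proportional.
#'
#' @param spec A [mito_phantom_spec()].
#' @return List: `mtg`, `tmrm` (each a [volume_image()]) and `truth`
#'   (`cell_mask`, `mito_mask`, `fraction`, `target_r`, `noise_sd`).
#' @export
gen_mito_volume <- function(spec) {
  stopifnot(inherits(spec, "mito_phantom_spec"))
  vs <- spec$voxel_size
  ext <- spec$cell_extent + 2 * spec$margin_um
  dims <- pmax(4L, round(ext / vs))
  cxs <- list((seq_len(dims[1]) - 0.5) * vs[1],
              (seq_len(dims[2]) - 0.5) * vs[2],
              (seq_len(dims[3]) - 0.5) * vs[3])
  lo <- rep(spec$margin_um, 3); hi <- lo + spec$cell_extent
  cell <- array(FALSE, dims)
  cell[which(cxs[[1]] >= lo[1] & cxs[[1]] <= hi[1]),
       which(cxs[[2]] >= lo[2] & cxs[[2]] <= hi[2]),
       which(cxs[[3]] >= lo[3] & cxs[[3]] <= hi[3])] <- TRUE

  f <- spec$mito_volume_fraction
  r <- spec$target_channel_correlation
  with_seed(spec$seed, {
    field <- blur3d(array(stats::rnorm(prod(dims)), dims),
                    spec$texture_sigma_um / vs)
    cut <- stats::quantile(field[cell], 1 - f, names = FALSE)
    mito <- cell & field > cut

    means <- spec$channel_means
    base <- 0.10 * means
    amp <- means - base
    rel_sd <- if (!is.null(spec$noise_sd)) {
      spec$noise_sd / amp
    } else {
      rep(sqrt(f * (1 - f) * (1 - r) / r), 2)
    }
    mk_channel <- function(k, name) {
      v <- array(0, dims)
      v[cell] <- base[k] + amp[k] * mito[cell]
      if (rel_sd[k] > 0) {
        v[cell] <- v[cell] +
          stats::rnorm(sum(cell), 0, rel_sd[k] * amp[k])
      }
      v[!cell] <- stats::rnorm(sum(!cell), 0, 0.005 * means[k])
      volume_image(v, vs, name)
    }
    mtg <- mk_channel(1, "mtg")
    tmrm <- mk_channel(2, "tmrm")
    realized_r <- stats::cor(mtg$voxels[cell], tmrm$voxels[cell])
    list(mtg = mtg, tmrm = tmrm,
         truth = list(cell_mask = cell, mito_mask = mito,
                      fraction = sum(mito) / sum(cell),
                      target_r = r, realized_r = realized_r,
                      noise_sd = rel_sd * amp))
  })
}
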